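# Default alkaloid scaffold queries: inclusion/exclusion substructure
# patterns plus curation blocklists. Patterns are package defaults validated
# against known alkaloids of each class; replace this file to run your own
# scaffolds. `core_smiles` is a plain SMILES of the scaffold core whose first
# atom can carry a substituent (used by the synthetic-report generator).
- name: benzylisoquinoline
  # 1-benzyl-1,2,3,4-tetrahydroisoquinoline core (higenamine, coclaurine, ...)
  inclusion: "C(c1ccccc1)C1NCCc2ccccc21"
  core_smiles: "C(c1ccccc1)C1NCCc2ccccc21"
  exclusions:
    # aporphine-type ring closure: counted under the aporphine scaffold
    - "N1CCc2cccc3c2C1Cc1ccccc1-3"
- name: aporphine
  # 4H-dibenzo[de,g]quinoline core (apomorphine, ...)
  inclusion: "N1CCc2cccc3c2C1Cc1ccccc1-3"
  core_smiles: "N1CCc2cccc3c2C1Cc1ccccc1-3"
  exclusions: []
- name: piperolactam
  # aristolactam core: phenanthrene-fused five-membered lactam; written with
  # generic atoms so the pattern matches whether or not the toolkit
  # aromatizes the lactam ring
  inclusion: "O=[#6]1[#7][#6]2[#6][#6][#6][#6]3[#6][#6][#6]4[#6][#6][#6][#6]1[#6]4[#6]23"
  core_smiles: "N1c2cccc3ccc4cccc(C1=O)c4c23"
  exclusions: []
- name: piperidine
  # saturated six-membered N-heterocycle (piperine, piperlongumine, ...)
  inclusion: "C1CCNCC1"
  core_smiles: "C1CCNCC1"
  exclusions:
    # fused bicyclics with a bridgehead nitrogen belong to other alkaloid
    # classes (quinolizidine, indolizidine)
    - "C1CCC2CCCCN2C1"
    - "C1CCN2CCCC2C1"
  blocklist:
    - species: "^Capsicum"
      compound: "N1CCCCC1"
      reason: "database error"
    - species: "^Centaurea[ _]aegyptica"
      compound: "."
      reason: "lack of NMR data in the original publication"
    - species: "^Aglaia[ _]perviridis"
      compound: "."
      reason: "lack of NMR data in the original publication"
- name: seco-benzylisoquinoline
  # ring-opened benzylisoquinoline: phenethylamine chain with an
  # ortho-benzyl substituent, amine not in a ring
  inclusion: "NCCc1ccccc1Cc1ccccc1"
  core_smiles: "NCCc1ccccc1Cc1ccccc1"
  exclusions:
    # intact tetrahydroisoquinoline ring means the compound is a cyclic
    # benzylisoquinoline, not a seco compound
    - "C1NCCc2ccccc21"
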