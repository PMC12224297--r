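# Default regulator subclass rules, evaluated in priority order (lower
# priority value first; first matching rule wins).
#
# A rule matches when at least one required_any set is fully present in the
# protein's domain set, no forbidden domain is present, and - for exact
# rules - the domain set equals the matched required set (duplicate copies
# of required domains are allowed).
#
# The four SARP rules follow the published subclass definitions. The
# remaining subclasses are approximate single-domain or documented-guess
# definitions (editable: derived from a curated combination table that is
# not reproduced here); replace them with your own curation for real runs.
rules:
  - name: SARP_large
    family: SARP
    priority: 10
    exact: false
    required_any:
      - [Trans_reg_C, BTAD, NB-ARC, TPR_10]
      - [Trans_reg_C, BTAD, NB-ARC, TPR_12]
    forbidden: []
  - name: SARP_LAL
    family: SARP
    priority: 20
    exact: false
    required_any:
      - [Trans_reg_C, BTAD, NB-ARC, AAA_16]
      - [Trans_reg_C, BTAD, NB-ARC, AAA_22]
    forbidden: []
  - name: SARP_medium
    family: SARP
    priority: 30
    exact: false
    required_any:
      - [Trans_reg_C, BTAD, NB-ARC]
    forbidden: []
  - name: SARP_small
    family: SARP
    priority: 40
    exact: true
    required_any:
      - [Trans_reg_C, BTAD]
    forbidden: []
  - name: PAS_LuxR_large
    family: LuxR
    priority: 50
    exact: false
    required_any:
      - [PAS, GerE, AAA_16]
      - [PAS, GerE, AAA_22]
    forbidden: []
    note: approximate size split; edit to match curation
  - name: PAS_LuxR_small
    family: LuxR
    priority: 60
    exact: false
    required_any:
      - [PAS, GerE]
    forbidden: [AAA_16, AAA_22]
    note: approximate size split; edit to match curation
  - name: LuxR_AAA_16
    family: LuxR
    priority: 70
    exact: false
    required_any:
      - [AAA_16, GerE]
    forbidden: [PAS, BTAD, Trans_reg_C]
  - name: TetR_C_33
    family: TetR
    priority: 80
    exact: true
    required_any:
      - [TetR_C_33]
  - name: ScbR
    family: TetR
    priority: 90
    exact: false
    required_any:
      - [TetR_N, Autoind_bind]
    note: approximate definition; edit to match curation
  - name: LitR
    family: LitR
    priority: 100
    exact: false
    required_any:
      - [MerR]
    note: approximate definition; edit to match curation
  - name: XRE
    family: XRE
    priority: 110
    exact: false
    required_any:
      - [HTH_3]
  - name: NrdR
    family: NrdR
    priority: 120
    exact: false
    required_any:
      - [ATP-cone]
  - name: LexA
    family: LexA
    priority: 130
    exact: false
    required_any:
      - [Peptidase_S24]
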