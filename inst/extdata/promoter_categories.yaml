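# Ordered promoter-category rules. Flags: sa_responsive, aba_responsive,
# drought_responsive, wrky_regulated. The first rule whose required flags
# are all set and forbidden flags all clear assigns the category;
# otherwise the promoter falls into the residual category.
rules:
  - category: 5          # every responsiveness class present, incl. W-box
    requires: [sa_responsive, aba_responsive, drought_responsive, wrky_regulated]
    forbids: []
  - category: 4          # coupled ABRE + DRE + SARE
    requires: [sa_responsive, aba_responsive, drought_responsive]
    forbids: []
  - category: 2          # SARE + coupled ABRE
    requires: [sa_responsive, aba_responsive]
    forbids: []
  - category: 3          # SARE + DRE, no coupled ABRE
    requires: [sa_responsive, drought_responsive]
    forbids: [aba_responsive]
  - category: 1          # SARE only
    requires: [sa_responsive]
    forbids: [aba_responsive, drought_responsive, wrky_regulated]
default_category: 6
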