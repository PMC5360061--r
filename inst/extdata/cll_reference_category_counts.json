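{
  "description": "Published category counts from a genome-wide comparison of prediagnostic CLL blood markers with a meta-analysis of clinical CLL studies; tier names: both_bonferroni = Bonferroni in both arms, prediag_bonferroni / clinical_bonferroni = Bonferroni in that arm and nominal in the other (for concordant labels) or Bonferroni in that arm with the other arm non-significant (for o+/o-, +o/-o), nominal_only = nominal significance only.",
  "universe": 11904,
  "clinical_bonferroni_total": 116,
  "prediag_bonferroni_total": 535,
  "categories": [
    {"label": "++", "tier": "both_bonferroni", "count": 1},
    {"label": "--", "tier": "both_bonferroni", "count": 8},
    {"label": "++", "tier": "prediag_bonferroni", "count": 106},
    {"label": "--", "tier": "prediag_bonferroni", "count": 62},
    {"label": "++", "tier": "clinical_bonferroni", "count": 6},
    {"label": "--", "tier": "clinical_bonferroni", "count": 55},
    {"label": "++", "tier": "nominal_only", "count": 284},
    {"label": "--", "tier": "nominal_only", "count": 576},
    {"label": "o+|o-", "tier": "prediag_bonferroni", "count": 192},
    {"label": "+o|-o", "tier": "clinical_bonferroni", "count": 41},
    {"label": "-+", "tier": "nominal_only", "count": 7},
    {"label": "+-", "tier": "nominal_only", "count": 25}
  ]
}
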