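{
  "schema_version": 1,
  "description": "Published diagnostic panels: 'differential' panels are VIP-ranked metabolites entering nested logistic models; 'tclass' panels are feature combinations chosen by forward selection under LOOCV.",
  "panels": [
    {
      "id": "diff_hc_vs_mdd",
      "comparison": ["HEALTHY", "MDD_ALL"],
      "method": "differential",
      "metabolites": ["Linoleic acid", "Cholesterol", "Glycine", "Galactose",
                      "Alanine", "Oleic acid", "Heptadecylic acid",
                      "Myoinositol", "Sorbitol"]
    },
    {
      "id": "diff_hc_vs_els",
      "comparison": ["HEALTHY", "ELS_MDD"],
      "method": "differential",
      "metabolites": ["Aspartic acid", "Glycine", "Linoleic acid", "Sorbitol",
                      "Myoinositol", "Mannose", "6-deoxy-mannopyrannose",
                      "Oleic acid", "Alanine"]
    },
    {
      "id": "diff_hc_vs_nonels",
      "comparison": ["HEALTHY", "NON_ELS_MDD"],
      "method": "differential",
      "metabolites": ["Cholesterol", "Linoleic acid", "Glycine"]
    },
    {
      "id": "diff_els_vs_nonels",
      "comparison": ["ELS_MDD", "NON_ELS_MDD"],
      "method": "differential",
      "metabolites": ["Cholesterol", "Glucopyranose", "Linoleic acid",
                      "Glyceric acid"]
    },
    {
      "id": "tclass_hc_vs_mdd",
      "comparison": ["HEALTHY", "MDD_ALL"],
      "method": "tclass",
      "learner": "naive_bayes",
      "metabolites": ["Valine", "Leucine", "Proline", "Glyceric acid",
                      "Pyroglutamate", "Galactose", "Glucopyranose",
                      "Palmitic acid", "Heptadecylic acid"]
    },
    {
      "id": "tclass_hc_vs_els",
      "comparison": ["HEALTHY", "ELS_MDD"],
      "method": "tclass",
      "metabolites": ["Lactic acid", "Proline", "Glyceric acid", "Mannose",
                      "Gluconate", "Tryptophane", "Stearic acid",
                      "Cholesterol"]
    },
    {
      "id": "tclass_hc_vs_nonels",
      "comparison": ["HEALTHY", "NON_ELS_MDD"],
      "method": "tclass",
      "metabolites": ["6-deoxy-mannopyrannose", "Palmitic acid",
                      "Heptadecylic acid"]
    },
    {
      "id": "tclass_els_vs_nonels",
      "comparison": ["ELS_MDD", "NON_ELS_MDD"],
      "method": "tclass",
      "metabolites": ["Oxalic acid", "Heptadecylic acid", "Stearic acid"]
    }
  ]
}
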