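[
  {"id": "goal",          "label": "Information portal for rare diseases",        "parent": null,        "queried": true},
  {"id": "medical",       "label": "Medical issues",                              "parent": "goal",      "queried": true},
  {"id": "research",      "label": "Research",                                    "parent": "goal",      "queried": true},
  {"id": "events",        "label": "Current events",                              "parent": "goal",      "queried": false},
  {"id": "social",        "label": "Social advisory and support services",        "parent": "goal",      "queried": true},
  {"id": "diagnosis",     "label": "Diagnosis",                                   "parent": "medical",   "queried": false},
  {"id": "treatment",     "label": "Treatment",                                   "parent": "medical",   "queried": false},
  {"id": "patterns",      "label": "Disease patterns",                            "parent": "medical",   "queried": false},
  {"id": "studies",       "label": "Current studies",                             "parent": "research",  "queried": false},
  {"id": "results",       "label": "Study results",                               "parent": "research",  "queried": false},
  {"id": "registries",    "label": "Registries",                                  "parent": "research",  "queried": false},
  {"id": "law",           "label": "Social law counseling",                       "parent": "social",    "queried": false},
  {"id": "psychosocial",  "label": "Psychosocial counseling",                     "parent": "social",    "queried": false},
  {"id": "selfhelp",      "label": "Self-help",                                   "parent": "social",    "queried": false},
  {"id": "diag_provider", "label": "Diagnosis: provider",                         "parent": "diagnosis", "queried": false},
  {"id": "diag_methods",  "label": "Diagnosis: methods",                          "parent": "diagnosis", "queried": false},
  {"id": "treat_provider","label": "Treatment: provider",                         "parent": "treatment", "queried": false},
  {"id": "treat_methods", "label": "Treatment: methods",                          "parent": "treatment", "queried": false},
  {"id": "aetiology",     "label": "Aetiology",                                   "parent": "patterns",  "queried": false},
  {"id": "frequency",     "label": "Frequency",                                   "parent": "patterns",  "queried": false},
  {"id": "symptoms",      "label": "Typical symptoms",                            "parent": "patterns",  "queried": false},
  {"id": "progression",   "label": "Progression",                                 "parent": "patterns",  "queried": false},
  {"id": "contacts_personal", "label": "Self-help: personal contacts",            "parent": "selfhelp",  "queried": false},
  {"id": "contacts_online",   "label": "Self-help: online contacts",              "parent": "selfhelp",  "queried": false}
]
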