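date,label
2022-12-01,FDA approval of Wegovy for adolescent (12-17 y) weight management
2023-08-01,Surge in media coverage of GLP-1 RAs across social platforms
2023-12-14,Celebrity endorsement of weight-loss medication
2024-03-01,Wegovy cardiovascular indication; Medicare Part D coverage expansion
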