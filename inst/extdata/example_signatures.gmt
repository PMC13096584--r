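exhaustion	CD8 Tex markers (example)	Pdcd1	Lag3	Tigit	Tox	Havcr2	Cxcl13
cv_zone	pericentral hepatocyte markers (example)	Cyp2e1	Glul	Oat	Cyp1a2	Slc1a2	Gulo
pv_zone	periportal hepatocyte markers (example)	Cyp2f2	Sds	Hal	Arg1	Pck1	Ass1
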