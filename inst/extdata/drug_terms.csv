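category_id,surface_form
semaglutide,semaglutide
ozempic,ozempic
ozempic,ozempy
wegovy,wegovy
tirzepatide,tirzepatide
mounjaro,mounjaro
zepbound,zepbound
glp1_class,GLP-1
glp1_class,GLP-1s
glp1_class,GLP-1 agonist
glp1_class,GLP-1 agonists
glp1_class,GLP-1 RA
glp1_class,GLP-1 RAs
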