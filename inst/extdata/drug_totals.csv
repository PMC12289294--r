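category_id,total_posts,total_ae_mentions
glp1_class,4885,1138
semaglutide,17146,1486
ozempic,18733,2579
wegovy,8527,1495
mounjaro,4031,868
tirzepatide,4202,436
zepbound,1769,169
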