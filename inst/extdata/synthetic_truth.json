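{"seed":2026,"scenario":"mid_peak","ranges":[{"taxon":"sp001","lo":514.0251153893,"hi":767.232516750212},{"taxon":"sp002","lo":0,"hi":204.689135539021},{"taxon":"sp003","lo":369.257051327781,"hi":515.200602173985},{"taxon":"sp004","lo":172.39266463625,"hi":664.122239096849},{"taxon":"sp005","lo":322.577806138479,"hi":512.201333978419},{"taxon":"sp006","lo":226.298735929518,"hi":578.307018493671},{"taxon":"sp007","lo":481.481102144309,"hi":591.197261517181},{"taxon":"sp008","lo":619.198941722203,"hi":718.783339671763},{"taxon":"sp009","lo":329.869746460508,"hi":421.642613779419},{"taxon":"sp010","lo":503.955523562569,"hi":699.518931137838},{"taxon":"sp011","lo":221.148058876984,"hi":360.046374450613},{"taxon":"sp012","lo":191.422679342697,"hi":320.285640708493},{"taxon":"sp013","lo":403.357723136366,"hi":714.369048577118},{"taxon":"sp014","lo":486.306069037537,"hi":595.458465743679},{"taxon":"sp015","lo":300.301920694665,"hi":432.877844424102},{"taxon":"sp016","lo":223.172231245928,"hi":521.849340861917},{"taxon":"sp017","lo":390.396418300513,"hi":693.166551345604},{"taxon":"sp018","lo":545.986894197349,"hi":800},{"taxon":"sp019","lo":149.361934311413,"hi":362.529940892434},{"taxon":"sp020","lo":147.048606968424,"hi":480.623223213725}],"belt_presence":{"sp001":[6,7,8],"sp002":[1,2,3],"sp003":[4,5,6],"sp004":[2,3,4,5,6,7],"sp005":[4,5,6],"sp006":[3,4,5,6],"sp007":[5,6],"sp008":[7,8],"sp009":[4,5],"sp010":[6,7],"sp011":[3,4],"sp012":[2,3,4],"sp013":[5,6,7,8],"sp014":[5,6],"sp015":[4,5],"sp016":[3,4,5,6],"sp017":[4,5,6,7],"sp018":[6,7,8],"sp019":[2,3,4],"sp020":[2,3,4,5]}}
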