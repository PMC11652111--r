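mountain_id,lo,area_km2
synthetic_toy,0,13.832437637131461
synthetic_toy,100,56.81440299959436
synthetic_toy,200,168.5324049588949
synthetic_toy,300,262.61173310594324
synthetic_toy,400,260.34690051983847
synthetic_toy,500,166.88319750862522
synthetic_toy,600,58.31864649557469
synthetic_toy,700,12.66027677439766
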