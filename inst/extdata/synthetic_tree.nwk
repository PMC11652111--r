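((((sp014:1.292272879,((sp006:0.1630142798,(sp015:0.065035339,sp007:0.065035339):0.09797894078):0.5835229322,((sp002:0.2012477451,sp003:0.2012477451):0.3096591042,(sp018:0.05075434939,sp019:0.05075434939):0.4601524998):0.2356303627):0.545735667):0.7717514831,sp010:2.064024362):0.07367057136,((sp016:0.02765700497,sp004:0.02765700497):0.2584177802,sp020:0.2860747851):1.851620148):0.3595320121,((((sp001:0.0005789842451,sp011:0.0005789842451):0.003707733853,sp008:0.004286718098):0.09200353446,sp012:0.09629025256):1.917708966,(sp005:1.996061649,(sp009:0.9127348301,(sp017:0.02769456007,sp013:0.02769456007):0.88504027):1.083326819):0.01793756884):0.4832277274);
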