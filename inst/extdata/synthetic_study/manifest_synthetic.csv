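probe_id,chr,pos,gene
probe_00001,chr1,1000,GENE1
probe_00002,chr1,2000,GENE1
probe_00003,chr1,3000,GENE2
probe_00004,chr1,4000,GENE2;GENEX
probe_00005,chr1,5000,GENE3
probe_00006,chr2,6000,GENE3
probe_00007,chr2,7000,GENE4
probe_00008,chr2,8000,GENE4;GENEX
probe_00009,chr2,9000,GENE5
probe_00010,chr2,10000,GENE5
probe_00011,chr3,11000,GENE6
probe_00012,chr3,12000,GENE6;GENEX
probe_00013,chr3,13000,GENE7
probe_00014,chr3,14000,GENE7
probe_00015,chr3,15000,GENE8
probe_00016,chr4,16000,GENE8;GENEX
probe_00017,chr4,17000,GENE9
probe_00018,chr4,18000,GENE9
probe_00019,chr4,19000,GENE10
probe_00020,chr4,20000,GENE10;GENEX
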