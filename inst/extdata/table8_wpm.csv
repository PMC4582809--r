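row_type,id,group,close,distant,living_close,living_distant,nonliving_close,nonliving_distant
patient,P2,vATL-damaged,42,82,47,83,37,80
patient,P3,vATL-damaged,80,95,77,93,83,97
patient,P4,vATL-damaged,60,72,57,77,63,67
patient,P5,vATL-damaged,75,98,73,97,77,100
patient,P6,vATL-damaged,65,95,57,93,73,97
patient,P8,vATL-damaged,70,98,70,100,70,97
patient,P9,vATL-intact,90,100,90,100,90,100
patient,P10,vATL-intact,75,97,73,97,77,97
patient,P12,vATL-intact,60,100,57,100,63,100
patient,P14,vATL-intact,80,100,83,100,77,100
group_mean,Mean,vATL-damaged,65,90,63,91,67,89
group_mean,Mean,vATL-intact,76,99,76,99,77,99
group_mean,Mean,Controls,80,96,78,96,82,96
group_sem,SEM,vATL-damaged,6,4,5,4,7,5
group_sem,SEM,vATL-intact,6,1,7,1,5,1
group_sem,SEM,Controls,2,1,2,1,2,1
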