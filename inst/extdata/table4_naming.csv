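row_type,id,group,all,living,nonliving,animal,tool,fruit_veg,vehicle
patient,P1,vATL-damaged,98,99,97,100,100,97,100
patient,P2,vATL-damaged,46,45,47,42,52,42,78
patient,P3,vATL-damaged,92,92,92,85,88,97,100
patient,P4,vATL-damaged,87,84,90,85,88,73,94
patient,P5,vATL-damaged,94,92,96,91,96,94,100
patient,P6,vATL-damaged,79,73,83,79,84,64,94
patient,P7,vATL-damaged,85,80,88,79,88,82,89
patient,P8,vATL-damaged,84,83,85,76,88,88,94
patient,P9,vATL-intact,98,98,98,97,100,97,100
patient,P10,vATL-intact,95,96,95,94,96,94,89
patient,P11,vATL-intact,88,90,87,88,84,94,100
patient,P12,vATL-intact,92,89,95,79,92,94,100
patient,P13,vATL-intact,95,97,93,94,92,100,100
patient,P14,vATL-intact,94,92,95,91,100,91,94
group_mean,Mean,vATL-damaged,83,81,85,80,86,80,94
group_mean,Mean,vATL-intact,94,93,94,90,94,95,97
group_mean,Mean,Controls,94,94,94,92,94,95,96
group_sem,SEM,vATL-damaged,5.7,5.9,5.6,6.0,5.1,6.8,2.7
group_sem,SEM,vATL-intact,1.3,1.5,1.5,2.6,2.5,1.3,1.9
group_sem,SEM,Controls,0.7,1.3,0.9,1.2,1.7,1.7,1.2
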