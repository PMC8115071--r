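group,case_id,n_neurons
PD,PD01,31
PD,PD02,44
PD,PD03,43
PD,PD04,26
PD,PD05,38
PD,PD06,36
PD,PD07,15
PD,PD08,40
PD,PD09,43
POLG,POLG01,44
POLG,POLG02,32
POLG,POLG03,27
POLG,POLG04,53
control,Con01,48
control,Con02,49
control,Con03,47
control,Con04,47
control,Con05,47
control,Con06,36
control,Con07,41
control,Con08,40
control,Con09,45
control,Con10,37
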