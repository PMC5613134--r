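model,term,environment,component,reported_share
GCA,female,13EX01,2.74,0.44
GCA,female,13EX03,1.68,0.5
GCA,female,13EX04,1.44,0.45
GCA,female,13EX05,2,0.5
GCA,female,14EX04,4.19,0.55
GCA,female,14RV01,3.7,0.52
GCA,female,15EX05,2.6,0.53
GCA,female,15EX06,1.58,0.43
GCA,female,15EX07,6.12,0.47
GCA,male,13EX01,1.44,0.23
GCA,male,13EX03,0.67,0.2
GCA,male,13EX04,0.75,0.23
GCA,male,13EX05,0.61,0.15
GCA,male,14EX04,1.66,0.22
GCA,male,14RV01,1.74,0.24
GCA,male,15EX05,0.88,0.18
GCA,male,15EX06,0.73,0.2
GCA,male,15EX07,2.91,0.22
GCA,residual,13EX01,2.09,NA
GCA,residual,13EX03,1.03,NA
GCA,residual,13EX04,1.03,NA
GCA,residual,13EX05,1.4,NA
GCA,residual,14EX04,1.79,NA
GCA,residual,14RV01,1.7,NA
GCA,residual,15EX05,1.4,NA
GCA,residual,15EX06,1.4,NA
GCA,residual,15EX07,4,NA
FM,female,13EX01,2.13,0.37
FM,female,13EX03,1.21,0.4
FM,female,13EX04,1.07,0.37
FM,female,13EX05,1.55,0.43
FM,female,14EX04,3.22,0.47
FM,female,14RV01,2.9,0.45
FM,female,15EX05,1.84,0.42
FM,female,15EX06,1.22,0.35
FM,female,15EX07,4.88,0.4
FM,male,13EX01,1.5,0.26
FM,male,13EX03,0.77,0.26
FM,male,13EX04,0.78,0.27
FM,male,13EX05,0.69,0.19
FM,male,14EX04,1.79,0.26
FM,male,14RV01,1.83,0.28
FM,male,15EX05,1.09,0.25
FM,male,15EX06,0.83,0.24
FM,male,15EX07,3.23,0.27
FM,residual,13EX01,2.08,NA
FM,residual,13EX03,1.03,NA
FM,residual,13EX04,1.03,NA
FM,residual,13EX05,1.39,NA
FM,residual,14EX04,1.79,NA
FM,residual,14RV01,1.7,NA
FM,residual,15EX05,1.4,NA
FM,residual,15EX06,1.4,NA
FM,residual,15EX07,4,NA
FMI,female,13EX01,2.13,0.37
FMI,female,13EX03,1.21,0.4
FMI,female,13EX04,1.07,0.37
FMI,female,13EX05,1.51,0.42
FMI,female,14EX04,3.22,0.47
FMI,female,14RV01,2.91,0.45
FMI,female,15EX05,1.84,0.42
FMI,female,15EX06,1.22,0.35
FMI,female,15EX07,4.88,0.4
FMI,male,13EX01,1.5,0.26
FMI,male,13EX03,0.78,0.26
FMI,male,13EX04,0.78,0.27
FMI,male,13EX05,0.72,0.2
FMI,male,14EX04,1.8,0.26
FMI,male,14RV01,1.84,0.29
FMI,male,15EX05,1.09,0.25
FMI,male,15EX06,0.83,0.24
FMI,male,15EX07,3.23,0.27
FMI,interaction,13EX01,0,0
FMI,interaction,13EX03,0.1,0.03
FMI,interaction,13EX04,0,0
FMI,interaction,13EX05,0.72,0.2
FMI,interaction,14EX04,0.14,0.02
FMI,interaction,14RV01,0.47,0.07
FMI,interaction,15EX05,0,0
FMI,interaction,15EX06,0,0
FMI,interaction,15EX07,0,0
FMI,residual,13EX01,2.08,NA
FMI,residual,13EX03,0.93,NA
FMI,residual,13EX04,1.03,NA
FMI,residual,13EX05,0.65,NA
FMI,residual,14EX04,1.64,NA
FMI,residual,14RV01,1.21,NA
FMI,residual,15EX05,1.4,NA
FMI,residual,15EX06,1.4,NA
FMI,residual,15EX07,4,NA
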