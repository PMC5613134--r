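scheme,model,environment,mean_ability
random_hybrids,GCA,13EX01,0.756
random_hybrids,GCA,13EX03,0.78
random_hybrids,GCA,13EX04,0.767
random_hybrids,GCA,13EX05,0.739
random_hybrids,GCA,14EX04,0.835
random_hybrids,GCA,14RV01,0.824
random_hybrids,GCA,15EX05,0.8
random_hybrids,GCA,15EX06,0.738
random_hybrids,GCA,15EX07,0.796
random_hybrids,GCA,MET,0.782
random_hybrids,FM,13EX01,0.762
random_hybrids,FM,13EX03,0.78
random_hybrids,FM,13EX04,0.768
random_hybrids,FM,13EX05,0.739
random_hybrids,FM,14EX04,0.836
random_hybrids,FM,14RV01,0.825
random_hybrids,FM,15EX05,0.8
random_hybrids,FM,15EX06,0.738
random_hybrids,FM,15EX07,0.797
random_hybrids,FM,MET,0.783
random_hybrids,FMI,13EX01,0.761
random_hybrids,FMI,13EX03,0.776
random_hybrids,FMI,13EX04,0.766
random_hybrids,FMI,13EX05,0.744
random_hybrids,FMI,14EX04,0.835
random_hybrids,FMI,14RV01,0.827
random_hybrids,FMI,15EX05,0.799
random_hybrids,FMI,15EX06,0.736
random_hybrids,FMI,15EX07,0.796
random_hybrids,FMI,MET,0.782
by_parents,GCA,13EX01,0.58
by_parents,GCA,13EX03,0.588
by_parents,GCA,13EX04,0.572
by_parents,GCA,13EX05,0.537
by_parents,GCA,14EX04,0.589
by_parents,GCA,14RV01,0.587
by_parents,GCA,15EX05,0.596
by_parents,GCA,15EX06,0.533
by_parents,GCA,15EX07,0.59
by_parents,GCA,MET,0.575
by_parents,FM,13EX01,0.653
by_parents,FM,13EX03,0.652
by_parents,FM,13EX04,0.641
by_parents,FM,13EX05,0.599
by_parents,FM,14EX04,0.665
by_parents,FM,14RV01,0.658
by_parents,FM,15EX05,0.634
by_parents,FM,15EX06,0.58
by_parents,FM,15EX07,0.635
by_parents,FM,MET,0.635
by_parents,FMI,13EX01,0.651
by_parents,FMI,13EX03,0.648
by_parents,FMI,13EX04,0.639
by_parents,FMI,13EX05,0.604
by_parents,FMI,14EX04,0.665
by_parents,FMI,14RV01,0.659
by_parents,FMI,15EX05,0.633
by_parents,FMI,15EX06,0.578
by_parents,FMI,15EX07,0.633
by_parents,FMI,MET,0.634
by_parents,FM_oil,13EX01,0.646
by_parents,FM_oil,13EX03,0.642
by_parents,FM_oil,13EX04,0.601
by_parents,FM_oil,13EX05,0.579
by_parents,FM_oil,14EX04,0.619
by_parents,FM_oil,14RV01,0.616
by_parents,FM_oil,15EX05,0.622
by_parents,FM_oil,15EX06,0.574
by_parents,FM_oil,15EX07,0.61
by_parents,FM_oil,MET,0.612
by_parents,mk_oil,13EX01,0.641
by_parents,mk_oil,13EX03,0.645
by_parents,mk_oil,13EX04,0.64
by_parents,mk_oil,13EX05,0.594
by_parents,mk_oil,14EX04,0.666
by_parents,mk_oil,14RV01,0.656
by_parents,mk_oil,15EX05,0.623
by_parents,mk_oil,15EX06,0.564
by_parents,mk_oil,15EX07,0.625
by_parents,mk_oil,MET,0.628
by_parents,mk_epi,13EX01,0.65
by_parents,mk_epi,13EX03,0.645
by_parents,mk_epi,13EX04,0.628
by_parents,mk_epi,13EX05,0.575
by_parents,mk_epi,14EX04,0.662
by_parents,mk_epi,14RV01,0.632
by_parents,mk_epi,15EX05,0.637
by_parents,mk_epi,15EX06,0.555
by_parents,mk_epi,15EX07,0.625
by_parents,mk_epi,MET,0.623
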