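indicator,group,age,gd_printed
ADL,non-lonely,65,6.9
ADL,non-lonely,70,7.7
ADL,non-lonely,75,8.5
ADL,non-lonely,80,9.2
ADL,non-lonely,85,9.7
ADL,non-lonely,90,9.6
ADL,non-lonely,95,8.6
ADL,non-lonely,99,7.1
ADL,lonely,65,6.0
ADL,lonely,70,6.8
ADL,lonely,75,7.8
ADL,lonely,80,8.7
ADL,lonely,85,9.6
ADL,lonely,90,10.0
ADL,lonely,95,9.5
ADL,lonely,99,8.2
SRH,non-lonely,65,3.6
SRH,non-lonely,70,3.5
SRH,non-lonely,75,3.5
SRH,non-lonely,80,3.5
SRH,non-lonely,85,3.4
SRH,non-lonely,90,3.4
SRH,non-lonely,95,3.3
SRH,non-lonely,99,3.3
SRH,lonely,65,4.3
SRH,lonely,70,4.2
SRH,lonely,75,4.2
SRH,lonely,80,4.2
SRH,lonely,85,4.2
SRH,lonely,90,4.2
SRH,lonely,95,4.1
SRH,lonely,99,4.1
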