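indicator,group,age,le,le_lower,le_upper,hle,hle_lower,hle_upper,ratio_printed
ADL,lonely,65,19.5,18.9,20.0,16.1,15.6,16.7,82.8
ADL,lonely,75,13.0,12.5,13.4,9.62,9.2,10.0,74.0
ADL,lonely,85,8.4,7.9,8.8,4.9,4.5,5.3,59.0
ADL,non-lonely,65,23.0,22.4,23.6,18.7,18.3,19.1,81.2
ADL,non-lonely,75,16.1,15.4,16.7,11.6,11.2,12.0,72.4
ADL,non-lonely,85,10.9,10.2,11.7,6.3,5.8,6.8,57.6
SRH,lonely,65,19.9,19.3,20.5,15.4,14.8,16.0,77.4
SRH,lonely,75,13.5,13.0,14.0,10.6,10.09,11.04,78.4
SRH,lonely,85,8.6,8.1,9.0,6.79,6.36,7.22,79.4
SRH,non-lonely,65,22.2,21.8,22.6,18.3,17.8,18.7,82.3
SRH,non-lonely,75,15.3,14.9,15.8,12.8,12.3,13.2,83.1
SRH,non-lonely,85,10.0,9.4,10.4,8.3,7.9,8.8,84.0
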