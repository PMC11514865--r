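indicator,group,gender,age,ratio
ADL,non-lonely,men,65,85.0
ADL,non-lonely,men,70,81.7
ADL,non-lonely,men,75,77.4
ADL,non-lonely,men,80,71.5
ADL,non-lonely,men,85,63.9
ADL,non-lonely,men,90,54.2
ADL,non-lonely,men,95,42.9
ADL,non-lonely,men,99,33.4
ADL,non-lonely,women,65,78.0
ADL,non-lonely,women,70,74.0
ADL,non-lonely,women,75,68.9
ADL,non-lonely,women,80,62.3
ADL,non-lonely,women,85,54.2
ADL,non-lonely,women,90,44.6
ADL,non-lonely,women,95,34.3
ADL,non-lonely,women,99,26.4
ADL,lonely,men,65,86.4
ADL,lonely,men,70,83.2
ADL,lonely,men,75,79.0
ADL,lonely,men,80,73.3
ADL,lonely,men,85,65.7
ADL,lonely,men,90,56.2
ADL,lonely,men,95,44.8
ADL,lonely,men,99,35.0
ADL,lonely,women,65,80.4
ADL,lonely,women,70,76.4
ADL,lonely,women,75,71.2
ADL,lonely,women,80,64.5
ADL,lonely,women,85,56.2
ADL,lonely,women,90,46.2
ADL,lonely,women,95,35.3
ADL,lonely,women,99,26.8
SRH,non-lonely,men,65,84.2
SRH,non-lonely,men,70,84.6
SRH,non-lonely,men,75,85.1
SRH,non-lonely,men,80,85.6
SRH,non-lonely,men,85,86.1
SRH,non-lonely,men,90,86.6
SRH,non-lonely,men,95,87.2
SRH,non-lonely,men,99,87.6
SRH,non-lonely,women,65,80.6
SRH,non-lonely,women,70,81.1
SRH,non-lonely,women,75,81.6
SRH,non-lonely,women,80,82.1
SRH,non-lonely,women,85,82.7
SRH,non-lonely,women,90,83.3
SRH,non-lonely,women,95,83.9
SRH,non-lonely,women,99,84.4
SRH,lonely,men,65,80.1
SRH,lonely,men,70,80.6
SRH,lonely,men,75,81.2
SRH,lonely,men,80,81.8
SRH,lonely,men,85,82.4
SRH,lonely,men,90,83.1
SRH,lonely,men,95,83.7
SRH,lonely,men,99,84.3
SRH,lonely,women,65,75.8
SRH,lonely,women,70,76.4
SRH,lonely,women,75,76.9
SRH,lonely,women,80,77.5
SRH,lonely,women,85,78.2
SRH,lonely,women,90,78.9
SRH,lonely,women,95,79.6
SRH,lonely,women,99,80.2
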