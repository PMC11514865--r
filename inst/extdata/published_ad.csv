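indicator,group,gender,ad_printed
ADL,non-lonely,men,51.5
ADL,non-lonely,women,51.7
ADL,lonely,men,51.4
ADL,lonely,women,53.6
SRH,non-lonely,men,-3.4
SRH,non-lonely,women,-3.7
SRH,lonely,men,-4.2
SRH,lonely,women,-4.4
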