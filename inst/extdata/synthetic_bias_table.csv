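profile_key,mean_logror,sd_logror
XLL,-0.09,0.09
LXL,-0.07,0.09
LLX,-0.11,0.10
XXL,-0.16,0.11
XLX,-0.20,0.12
LXX,-0.18,0.12
XXX,-0.27,0.13
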