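session,observed_system_s,observed_manual_s
night01,64800,51000
night02,64800,53820
night03,64800,55320
night04,64800,58020
night05,64800,49800
night06,32400,29640
night07,64800,55140
night08,64800,66540
night09,64800,61140
night10,64800,53460
night11,64800,80760
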