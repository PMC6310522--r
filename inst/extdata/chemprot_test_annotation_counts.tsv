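class	evaluated	annotations
CPR:1	no	215
CPR:2	no	1743
CPR:3	yes	667
CPR:4	yes	1667
CPR:5	yes	198
CPR:6	yes	293
CPR:7	no	25
CPR:8	no	25
CPR:9	yes	644
CPR:10	no	267
negative	no	10025
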