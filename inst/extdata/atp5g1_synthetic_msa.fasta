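>ags|SYNP01|ATP5G1
IYNEFWGFIDYPPE-MRNPLHVETNLSDEGCALYDWGIAPICIELLKGEGRAQGLTLMEMLSKRFACNRN
>itr|SYNP02|ATP5G1
IYNEFWGFIDYPPE-MRNPLHVETNLSDEGCALYDWGIAPICIELLKGEGRAQGLTLMEMLSKRFACNRN
>mmu|SYNP03|ATP5G1
ISNEFWG--DYPPCFMRNPLHVETNFSDEGCAPQNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>rno|SYNP04|ATP5G1
IYNAFWG--DTPPEFMRNPLHVETNLSDEGCAPLNWGIATICIELLKGCGRAQGLTLMEMLSKRFACNRN
>sar|SYNP05|ATP5G1
IYNQFWG--DRPPEFMRNPLHVCTNLSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>pab|SYNP06|ATP5G1
IYNEFWG--DYPPEFMRNPLHVETNNSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>hsa|SYNP07|ATP5MC1
IYNEFWG--DYPPEFMRNPLHVETNLSDEGCAPYNWGIATICIELLKGPGRAQGLTLMEMLSKRFACNRN
>eca|SYNP08|ATP5G1
IVNEFWG--DDPPEFMRNPLHVGTNLSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>bta|SYNP09|ATP5G1
IYNEFWG--DYPPRFMRNPLHVKTNTSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>ocu|SYNP10|ATP5G1
INNYFWG--DPPPEFMRNPLHVWTNLSDEGCAPFNWGIATICSELLKGLGRAQGLTLMEMLSKRFACNRN
>ssc|SYNP11|ATP5G1
IMNEFWG--DYPPEFMRNPLHVETNLSDEGCAPPNWGIATICMELLKGEGRAQGLTLMEMLSKRFACNRN
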