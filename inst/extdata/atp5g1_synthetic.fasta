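>ags|SYNP01|ATP5G1
IYNEFWGFIDYPPEMRNPLHVETNLSDEGCALYDWGIAPICIELLKGEGRAQGLTLMEMLSKRFACNRN
>itr|SYNP02|ATP5G1
IYNEFWGFIDYPPEMRNPLHVETNLSDEGCALYDWGIAPICIELLKGEGRAQGLTLMEMLSKRFACNRN
>mmu|SYNP03|ATP5G1
ISNEFWGDYPPCFMRNPLHVETNFSDEGCAPQNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>rno|SYNP04|ATP5G1
IYNAFWGDTPPEFMRNPLHVETNLSDEGCAPLNWGIATICIELLKGCGRAQGLTLMEMLSKRFACNRN
>sar|SYNP05|ATP5G1
IYNQFWGDRPPEFMRNPLHVCTNLSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>pab|SYNP06|ATP5G1
IYNEFWGDYPPEFMRNPLHVETNNSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>hsa|SYNP07|ATP5MC1
IYNEFWGDYPPEFMRNPLHVETNLSDEGCAPYNWGIATICIELLKGPGRAQGLTLMEMLSKRFACNRN
>eca|SYNP08|ATP5G1
IVNEFWGDDPPEFMRNPLHVGTNLSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>bta|SYNP09|ATP5G1
IYNEFWGDYPPRFMRNPLHVKTNTSDEGCAPYNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
>ocu|SYNP10|ATP5G1
INNYFWGDPPPEFMRNPLHVWTNLSDEGCAPFNWGIATICSELLKGLGRAQGLTLMEMLSKRFACNRN
>ssc|SYNP11|ATP5G1
IMNEFWGDYPPEFMRNPLHVETNLSDEGCAPPNWGIATICMELLKGEGRAQGLTLMEMLSKRFACNRN
>ags|SYNP90|ATP5G1
IYNEFWHFIDYPPEMRNPLHVETNLSDEGCALYDWKIAPICIELLKGEGRAQGGTGMEMLSKRFACNRN
>mmu|SYNP91|ATP5G2
ISNEFWGDYPPCFMRNPLHVETNFSDEGCAPQNWGIATICIELLKGEGRAQGLTLMEMLSKRFACNRN
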