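v01,v02
v01,v03
v01,v04
v01,v05
v01,v06
v01,v07
v01,v08
v01,v09
v01,v11
v01,v12
v01,v13
v01,v14
v01,v18
v01,v20
v01,v22
v01,v32
v02,v03
v02,v04
v02,v08
v02,v14
v02,v18
v02,v20
v02,v22
v02,v31
v03,v04
v03,v08
v03,v09
v03,v10
v03,v14
v03,v28
v03,v29
v03,v33
v04,v08
v04,v13
v04,v14
v05,v07
v05,v11
v06,v07
v06,v11
v06,v17
v07,v17
v09,v31
v09,v33
v09,v34
v10,v34
v14,v34
v15,v33
v15,v34
v16,v33
v16,v34
v19,v33
v19,v34
v20,v34
v21,v33
v21,v34
v23,v33
v23,v34
v24,v26
v24,v28
v24,v30
v24,v33
v24,v34
v25,v26
v25,v28
v25,v32
v26,v32
v27,v30
v27,v34
v28,v34
v29,v32
v29,v34
v30,v33
v30,v34
v31,v33
v31,v34
v32,v33
v32,v34
v33,v34
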