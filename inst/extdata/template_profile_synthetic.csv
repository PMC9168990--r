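subclass,glycoform,weight
IgG1,G0,2.10
IgG1,G0F,12.00
IgG1,G0N,0.48
IgG1,G0NF,2.40
IgG1,G0-NF,0.72
IgG1,G1,1.80
IgG1,G1F,16.80
IgG1,G1FS,2.10
IgG1,G1-N,0.30
IgG1,G1N,0.48
IgG1,G1NF,2.40
IgG1,G1-NF,0.48
IgG1,G1NFS,0.60
IgG1,G1S,0.60
IgG1,G2,0.90
IgG1,G2F,7.80
IgG1,G2FS,3.00
IgG1,G2N,0.30
IgG1,G2NF,1.20
IgG1,G2NFS,0.48
IgG1,G2S,0.48
IgG1,G2S2,0.36
IgG2,G0,1.12
IgG2,G0F,6.40
IgG2,G0N,0.26
IgG2,G0NF,1.28
IgG2,G0-NF,0.38
IgG2,G1,0.96
IgG2,G1F,8.96
IgG2,G1FS,1.12
IgG2,G1-N,0.16
IgG2,G1N,0.26
IgG2,G1NF,1.28
IgG2,G1-NF,0.26
IgG2,G1NFS,0.32
IgG2,G1S,0.32
IgG2,G2,0.48
IgG2,G2F,4.16
IgG2,G2FS,1.60
IgG2,G2N,0.16
IgG2,G2NF,0.64
IgG2,G2NFS,0.26
IgG2,G2S,0.26
IgG2,G2S2,0.19
IgG3/4,G0,0.28
IgG3/4,G0F,1.60
IgG3/4,G0N,0.06
IgG3/4,G0NF,0.32
IgG3/4,G0-NF,0.10
IgG3/4,G1,0.24
IgG3/4,G1F,2.24
IgG3/4,G1FS,0.28
IgG3/4,G1-N,0.04
IgG3/4,G1N,0.06
IgG3/4,G1NF,0.32
IgG3/4,G1-NF,0.06
IgG3/4,G1NFS,0.08
IgG3/4,G1S,0.08
IgG3/4,G2,0.12
IgG3/4,G2F,1.04
IgG3/4,G2FS,0.40
IgG3/4,G2N,0.04
IgG3/4,G2NF,0.16
IgG3/4,G2NFS,0.06
IgG3/4,G2S,0.06
IgG3/4,G2S2,0.05
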