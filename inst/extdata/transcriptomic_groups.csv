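line_label,group
Pvalb,PV
Sst,non-PV inhibitory
Vip,non-PV inhibitory
Htr3a,non-PV inhibitory
Ndnf,non-PV inhibitory
Lamp5,non-PV inhibitory
Chat,non-PV inhibitory
Chrna2,non-PV inhibitory
Nkx2,non-PV inhibitory
Nos1,non-PV inhibitory
Gad2,mixed
Slc32a1,mixed
Oxtr,mixed
Penk,mixed
Tnnt1,mixed
Nr5a1,excitatory
Scnn1a,excitatory
Rorb,excitatory
Cux2,excitatory
Ntsr1,excitatory
Rbp4,excitatory
Ctgf,excitatory
Tlx3,excitatory
Sim1,excitatory
Esr2,excitatory
Glt25d2,excitatory
Slc17a6,excitatory
Slc17a7,excitatory
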