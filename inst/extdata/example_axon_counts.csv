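pathway,region,ap_mm,nucleus,count
MC-RN,diencephalon,-1.30,PO,34
MC-RN,diencephalon,-1.30,VM,21
MC-RN,diencephalon,-1.30,ZI,12
MC-RN,diencephalon,-1.42,PO,41
MC-RN,diencephalon,-1.42,VM,25
MC-RN,diencephalon,-1.42,PF,9
MC-RN,diencephalon,-1.55,PO,28
MC-RN,diencephalon,-1.55,ZI,15
MC-RN,diencephalon,-1.55,LP,6
MC-RN,diencephalon,-1.80,PO,17
MC-RN,diencephalon,-1.80,VM,11
MC-RN,diencephalon,-2.10,PO,8
MC-RN,diencephalon,-2.10,PF,4
MC-RN,diencephalon,-2.40,PO,3
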