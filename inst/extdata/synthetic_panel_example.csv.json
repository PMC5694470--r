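{"source":"synthetic","concentration_unit":"nM","assumed_zero_channels":{"SYN001":["INa_fast","IKs","IK1","Ito"],"SYN002":["INa_fast","IKs","IK1","Ito"],"SYN003":["INa_fast","IKs","IK1","Ito"],"SYN004":["INa_fast","IKs","IK1","Ito"],"SYN005":["INa_fast","IKs","IK1","Ito"],"SYN006":["INa_fast","IKs","IK1","Ito"],"SYN007":["INa_fast","IKs","IK1","Ito"],"SYN008":["INa_fast","IKs","IK1","Ito"],"SYN009":["INa_fast","IKs","IK1","Ito"],"SYN010":["INa_fast","IKs","IK1","Ito"],"SYN011":["INa_fast","IKs","IK1","Ito"],"SYN012":["INa_fast","IKs","IK1","Ito"]}}
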