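v_target_0back:
  location: 2.9867554
  scale: 1.6239008
  lower: -10.0
  upper: 10.0
v_novel_0back:
  location: 3.3830274
  scale: 1.3371644
  lower: -10.0
  upper: 10.0
v_lure_0back:
  location: 2.6993629
  scale: 1.4457564
  lower: -10.0
  upper: 10.0
a_0back:
  location: 1.2153798
  scale: 0.5464449
  lower: 0.001
  upper: 10.0
t0_0back:
  location: 0.3434455
  scale: 0.0581882
  lower: 0.05
  upper: 1.0
st0_0back:
  location: 0.1652559
  scale: 0.0959743
  lower: 0.0
  upper: 1.0
z_0back:
  location: 0.5203522
  scale: 0.1302781
  lower: 0.1
  upper: 0.9
p_contam_0back:
  location: 0.0049169
  scale: 0.0672808
  lower: 0.0
  upper: 0.5
v_target_2back:
  location: 1.8166127
  scale: 1.1882526
  lower: -10.0
  upper: 10.0
v_novel_2back:
  location: 2.4474346
  scale: 1.074162
  lower: -10.0
  upper: 10.0
v_lure_2back:
  location: 1.3182027
  scale: 1.0780347
  lower: -10.0
  upper: 10.0
a_2back:
  location: 1.343073
  scale: 0.4305257
  lower: 0.001
  upper: 10.0
t0_2back:
  location: 0.3824581
  scale: 0.0683164
  lower: 0.05
  upper: 1.0
st0_2back:
  location: 0.1430988
  scale: 0.1502904
  lower: 0.0
  upper: 1.0
z_2back:
  location: 0.5173241
  scale: 0.111927
  lower: 0.1
  upper: 0.9
p_contam_2back:
  location: -0.0145209
  scale: 0.0777764
  lower: 0.0
  upper: 0.5
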