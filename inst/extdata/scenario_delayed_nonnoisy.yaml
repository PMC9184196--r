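variant: delayed_nonnoisy
'n': 5
r:
- 10.0
- 10.19999999999999929
- 10.40000000000000036
- 10.59999999999999964
- 10.80000000000000071
b:
- 1.0
- 1.00099999999999989
- 1.002
- 1.00299999999999989
- 1.004
c:
- 0.001
- 0.002
- 0.003
- 0.004
- 0.005
ees_A: 0.10000000000000001
ees_f: 0.129
dist_amplitude:
- 0.001
- 0.002
- 0.003
- 0.004
- 0.005
dist_rate:
- 0.20000000000000001
- 0.20000000000000001
- 0.20000000000000001
- 0.20000000000000001
- 0.20000000000000001
coupling:
- - -0.0010735
  - 0.00036412
  - 0.00040396
  - 2.06399999999999989e-05
  - 2.84809999999999979e-04
- - 0.00036412
  - -0.001507
  - 0.00083269
  - 0.00016223
  - 0.00014797
- - 0.00040396
  - 0.00083269
  - -0.0022451
  - 0.00081832
  - 0.00019013
- - 2.06399999999999989e-05
  - 1.62229999999999997e-04
  - 8.18319999999999985e-04
  - -1.63710000000000006e-03
  - 6.35959999999999976e-04
- - 0.00028481
  - 0.00014797
  - 0.00019013
  - 0.00063596
  - -0.0012589
tau1: 0.20000000000000001
tau2: 0.20000000000000001
drive_ic:
- 0.0
- 0.05
- 0.05
- 0.0
- 0.05
- 0.10000000000000001
- 0.20000000000000001
- 0.20000000000000001
- 0.10000000000000001
- 0.20000000000000001
slave_ic:
- 0.0
- 0.05
- 0.05
- 0.0
- 0.05
- 0.10000000000000001
- 0.20000000000000001
- 0.20000000000000001
- 0.10000000000000001
- 0.20000000000000001
slave_ic_perturbation: 0.001
law: delayed
t_on: 110.0
gain_columns:
- 1
- 2
t_end: 250.0
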