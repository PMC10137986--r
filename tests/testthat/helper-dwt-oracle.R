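# Single-step DWT reference coefficients computed independently with an
# established wavelet library (PyWavelets 1.9.0, db5), frozen here so the
# filter-bank implementation is checked against an external oracle.
dwt_oracle <- list(
  n8 = list(
    x = c(
    1.3468880000000001, -0.020636999999999999, 0.141067,
    0.38353999999999999, -0.97844699999999996, 1.27898,
    -1.3791929999999999, -0.027219),
    sym_cA = c(
    -0.17072301409372617, -0.023034649687568853, 0.017531914061600991,
    1.6695232312404966, 0.4432053506294461, 0.044718692246571885,
    -0.23506366081940336, -0.69259845809427067),
    sym_cD = c(
    -0.089537386536037669, 0.53079907458286901, -1.2035840152784141,
    -1.7918086275507796, 0.34821349258275697, 1.8741978814835143,
    0.78500444875497499, -0.45328486803888435),
    per_cA = c(
    -0.68764907620567972, 0.62228913142506204, 0.43044982084317568,
    0.16168982667901521),
    per_cD = c(
    -1.0787404818396671, -1.8136276965389142, 0.96043144563373639,
    0.17523670801082694)
  ),
  n13 = list(
    x = c(
    1.0347040000000001, 0.271505, 0.36810799999999999,
    0.46057599999999999, -0.27037600000000001, -0.288495,
    1.183716, -0.50673900000000005, 1.2953600000000001,
    -0.062190000000000002, 0.29659600000000003, 1.247592,
    0.57348399999999999),
    sym_cA = c(
    0.26627166245685951, 0.15143199863353679, 0.40456031823682531,
    1.3154849173294478, 0.81327628228514648, -0.067894436929906932,
    0.26780397283629676, 0.72727157614593341, 0.49995253803410922,
    0.98114967517212293, 1.3121318842366372),
    sym_cD = c(
    -0.020229761131726833, 0.30126943605142331, -0.44308514073171412,
    1.0535537301480644, 1.2306875315560251, 0.07384970571652065,
    -0.63756209789974827, 0.65688786178694247, -0.2616974332373237,
    -1.4420938962911842, -0.76423838314532011),
    per_cA = c(
    1.0642450441918319, 1.0853343435514369, 0.81327628228514648,
    -0.067894436929906932, 0.26780397283629676, 0.72986617059437608,
    0.47539702056400901),
    per_cD = c(
    -0.39867483745693022, 1.0487585546970297, 1.2306875315560251,
    0.07384970571652065, -0.63756209789974827, 0.5323569854659288,
    0.1204839482507479)
  )
)
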