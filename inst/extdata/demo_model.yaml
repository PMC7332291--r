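schema: pyloric-model/1
name: demo-s101-chunked-best
cells:
  PD:
    gNa: 232.232232232232234992
    gCaT: 5.305305305305305197
    gCaS: 36.536536536536537767
    gA: 66.866866866866871533
    gKCa: 16.016016016016017431
    gKd: 97.997997997997998709
    gH: 14.214214214214214493
    gleak: 0.270270270270270285
    tauCa: 590.590590590590636566
  LP:
    gNa: 232.232232232232234992
    gCaT: 5.80580580580580552
    gCaS: 36.336336336336337638
    gA: 73.473473473473475792
    gKCa: 15.01501501501501501
    gKd: 99.699699699699692701
    gH: 11.911911911911911233
    gleak: 0.270270270270270285
    tauCa: 1453.453453453453448674
  PY:
    gNa: 235.235235235235222717
    gCaT: 6.206206206206205778
    gCaS: 40.040040040040040026
    gA: 77.177177177177171075
    gKCa: 16.016016016016017431
    gKd: 98.598598598598599096
    gH: 14.214214214214214493
    gleak: 0.230230230230230232
    tauCa: 1541.541541541541619154
synapses:
  PD.LP.glut: 0.031381381381381385
  PD.LP.chol: 0.048648648648648651
  PD.PY.glut: 0.002602602602602603
  PD.PY.chol: 0.002652652652652653
  LP.PD.glut: 0.048848848848848853
  LP.PY.glut: 0.048848848848848853
  PY.LP.glut: 0.015265265265265265
q10:
  gNa: 1.469469469469469436
  gCaT: 1.333333333333333259
  gCaS: 1.0
  gA: 1.580580580580580596
  gKCa: 1.004004004004003914
  gKd: 1.905905905905906028
  gH: 1.0
  gleak: 1.036036036036036112
  tau.Na.m: 1.618618618618618665
  tau.Na.h: 3.297297297297297369
  tau.CaT.m: 1.618618618618618665
  tau.CaT.h: 1.159159159159159236
  tau.CaS.m: 1.588588588588588646
  tau.CaS.h: 1.603603603603603656
  tau.A.m: 2.399399399399399613
  tau.A.h: 1.066066066066066131
  tau.KCa.m: 1.588588588588588646
  tau.Kd.m: 1.600600600600600609
  tau.H.m: 1.021021021021021102
  tauCa: 1.696696696696696538
  gsyn.glut: 1.849849849849849903
  gsyn.chol: 1.286286286286286273
  tausyn.glut: 1.009009009009008917
  tausyn.chol: 1.780780780780780725
provenance:
  stage1_seed: 101
  stage1_population: 200
  stage1_generations: 400
  stage1_model_rank: 1
  stage2_chunk_seeds:
  - 701
  - 702
  - 703
  - 704
  stage2_population: 64
  stage2_generations_per_chunk: 50
  note: best thermal-objective candidate of the reduced search; committed without
    passing the full intermediate screen
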