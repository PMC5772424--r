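# Default demographic model priors.
#
# Sizes (N_*) are effective diploid individuals; loguniform bounds are
# base-10 exponents.  Times (T_*) are generations before sampling, uniform.
# mu is the mean per-locus per-generation microsatellite mutation rate
# (loguniform over 1e-5..1e-3); p_gsm is the geometric multistep proportion
# of the generalized stepwise mutation model.  T_split for the fragmented
# models is uniform on (0, T_shrink] (drawn as a fraction of T_shrink).
#
# AC / RI / ACS / RIS priors follow the published table; ID, ED and TI
# priors are package defaults (see the methods vignette).
generation_time_years: 15
models:
  ID:
    demes: 1
    priors:
      N_Anc:    {kind: loguniform, min: 4, max: 5}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 20, max: 1500}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  ED:
    demes: 1
    priors:
      N_Anc:    {kind: loguniform, min: 4, max: 5}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 20, max: 1500}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  AC:
    demes: 1
    priors:
      N_Anc:    {kind: loguniform, min: 4, max: 5}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 1000, max: 1500}
      N_shrink: {kind: uniform, min: 4, max: 50}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  RI:
    demes: 1
    priors:
      N_Anc:    {kind: loguniform, min: 2.4, max: 4}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 20, max: 70}
      N_shrink: {kind: uniform, min: 2, max: 50}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  TI:
    demes: 1
    priors:
      N_Anc:    {kind: loguniform, min: 4, max: 5}
      N_Sulu:   {kind: loguniform, min: 2.4, max: 4}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 20, max: 70}
      N_shrink: {kind: uniform, min: 2, max: 50}
      T_first:  {kind: uniform, min: 40, max: 70}
      N_shrink1: {kind: uniform, min: 2, max: 50}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  ACS:
    demes: 4
    priors:
      N_Anc:    {kind: loguniform, min: 4, max: 5}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 1000, max: 1500}
      N_shrink: {kind: uniform, min: 8, max: 50}
      T_split:  {kind: uniform, min: 0, max: 1, scale_by: T_shrink}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
  RIS:
    demes: 4
    priors:
      N_Anc:    {kind: loguniform, min: 2.4, max: 4}
      N_Cur:    {kind: loguniform, min: 2.4, max: 3}
      T_shrink: {kind: uniform, min: 20, max: 70}
      N_shrink: {kind: uniform, min: 8, max: 50}
      T_split:  {kind: uniform, min: 0, max: 1, scale_by: T_shrink}
      mu:       {kind: loguniform, min: -5, max: -3}
      p_gsm:    {kind: uniform, min: 0, max: 0.3}
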