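# Synthetic reconstruction of an EGFR signaling rule-based model
# (egf / egfr / Grb2 / Shc / Sos; 24 reaction rules).
begin model
begin parameters
  egf_tot   1.2e6
  egfr_tot  1.8e5
  kp1 1.667e-06
  km1 0.06
  kp2 5.556e-06
  km2 0.1
  kp3 0.5
  km3 4.505
  kp4 0.5
  km4 4.505
  kp5 8.333e-07
  km5 0.05
  kp10 6.0
  km10 0.06
  kp15 5.556e-08
  km15 1.5
end parameters
begin molecule types
  egf(r)
  egfr(l,r,Y1068~Y~pY,Y1148~Y~pY)
  Grb2(SH2,SH3)
  Shc(PTB,Y317~Y~pY)
  Sos(dom)
end molecule types
begin seed species
  egf(r) egf_tot
  egfr(l,r,Y1068~Y,Y1148~Y) egfr_tot
  Grb2(SH2,SH3) 1.0e5
  Shc(PTB,Y317~Y) 2.7e5
  Sos(dom) 1.3e5
end seed species
begin observables
  Molecules egfr_tot_obs egfr()
  Molecules Shc_pY Shc(Y317~pY)
  Molecules RecGrb2 egfr(Y1068~pY!1).Grb2(SH2!1)
end observables
begin reaction rules
  egf(r) + egfr(l,r) <-> egf(r!1).egfr(l!1,r) kp1, km1
  egfr(l!+,r) + egfr(l!+,r) <-> egfr(l!+,r!1).egfr(l!+,r!1) kp2, km2
  egfr(r!+,Y1068~Y) -> egfr(r!+,Y1068~pY) kp3
  egfr(Y1068~pY) -> egfr(Y1068~Y) km3
  egfr(r!+,Y1068~pY) -> egfr(r!+,Y1068~Y) km3
  egfr(r!+,Y1148~Y) -> egfr(r!+,Y1148~pY) kp4
  egfr(Y1148~pY) -> egfr(Y1148~Y) km4
  egfr(r!+,Y1148~pY) -> egfr(r!+,Y1148~Y) km4
  egfr(Y1068~pY) + Grb2(SH2,SH3) <-> egfr(Y1068~pY!1).Grb2(SH2!1,SH3) kp5, km5
  egfr(Y1068~pY) + Grb2(SH2,SH3!+) <-> egfr(Y1068~pY!1).Grb2(SH2!1,SH3!+) kp5, km5
  egfr(Y1148~pY) + Shc(PTB,Y317~Y) <-> egfr(Y1148~pY!1).Shc(PTB!1,Y317~Y) kp5, km5
  egfr(Y1148~pY) + Shc(PTB,Y317~pY) <-> egfr(Y1148~pY!1).Shc(PTB!1,Y317~pY) kp5, km5
  egfr(Y1148~pY) + Shc(PTB,Y317~pY!+) <-> egfr(Y1148~pY!1).Shc(PTB!1,Y317~pY!+) kp5, km5
  Shc(PTB!+,Y317~Y) -> Shc(PTB!+,Y317~pY) kp10
  Shc(PTB!+,Y317~pY) -> Shc(PTB!+,Y317~Y) km10
  Shc(PTB,Y317~pY) -> Shc(PTB,Y317~Y) km10
  Shc(Y317~pY) + Grb2(SH2,SH3) <-> Shc(Y317~pY!1).Grb2(SH2!1,SH3) kp15, km15
  Shc(Y317~pY) + Grb2(SH2,SH3!+) <-> Shc(Y317~pY!1).Grb2(SH2!1,SH3!+) kp15, km15
  Shc(PTB!+,Y317~pY) + Grb2(SH2,SH3) <-> Shc(PTB!+,Y317~pY!1).Grb2(SH2!1,SH3) kp15, km15
  Shc(PTB!+,Y317~pY) + Grb2(SH2,SH3!+) <-> Shc(PTB!+,Y317~pY!1).Grb2(SH2!1,SH3!+) kp15, km15
  Grb2(SH2,SH3) + Sos(dom) <-> Grb2(SH2,SH3!1).Sos(dom!1) kp15, km15
  Grb2(SH2!+,SH3) + Sos(dom) <-> Grb2(SH2!+,SH3!1).Sos(dom!1) kp15, km15
  Shc(Y317~pY!1).Grb2(SH2!1,SH3) + Sos(dom) <-> Shc(Y317~pY!1).Grb2(SH2!1,SH3!2).Sos(dom!2) kp15, km15
  egfr(Y1068~pY!1).Grb2(SH2!1,SH3) + Sos(dom) <-> egfr(Y1068~pY!1).Grb2(SH2!1,SH3!2).Sos(dom!2) kp15, km15
end reaction rules
end model
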