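# Synthetic EGFR-family variant without the Shc branch.
begin model
begin parameters
  kp1 1.667e-06
  km1 0.06
  kp2 5.556e-06
  km2 0.1
  kp3 0.5
  km3 4.505
  kp5 8.333e-07
  km5 0.05
end parameters
begin molecule types
  egf(r)
  egfr(l,r,Y1068~Y~pY)
  Grb2(SH2,SH3)
  Sos(dom)
end molecule types
begin seed species
  egf(r) 1.2e6
  egfr(l,r,Y1068~Y) 1.8e5
  Grb2(SH2,SH3) 1.0e5
  Sos(dom) 1.3e5
end seed species
begin observables
  Molecules RecGrb2 egfr(Y1068~pY!1).Grb2(SH2!1)
end observables
begin reaction rules
  egf(r) + egfr(l,r) <-> egf(r!1).egfr(l!1,r) kp1, km1
  egfr(l!+,r) + egfr(l!+,r) <-> egfr(l!+,r!1).egfr(l!+,r!1) kp2, km2
  egfr(r!+,Y1068~Y) -> egfr(r!+,Y1068~pY) kp3
  egfr(Y1068~pY) -> egfr(Y1068~Y) km3
  egfr(Y1068~pY) + Grb2(SH2,SH3) <-> egfr(Y1068~pY!1).Grb2(SH2!1,SH3) kp5, km5
  Grb2(SH2,SH3) + Sos(dom) <-> Grb2(SH2,SH3!1).Sos(dom!1) kp5, km5
  Grb2(SH2!+,SH3) + Sos(dom) <-> Grb2(SH2!+,SH3!1).Sos(dom!1) kp5, km5
end reaction rules
end model
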