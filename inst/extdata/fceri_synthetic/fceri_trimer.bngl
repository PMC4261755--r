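# Synthetic FceRI-family variant with a trivalent ligand.
begin model
begin parameters
  kp1 1.3e-07
  km1 0.01
  kp2 2.5e-06
  km2 0.05
  pLb 30
  dm  0.1
  pLS 100
  dc  0.1
end parameters
begin molecule types
  Lig(l,l,l)
  Lyn(U,SH2)
  Syk(tSH2,lytk~Y~pY,aloop~Y~pY)
  Rec(a,b~Y~pY,g~Y~pY)
end molecule types
begin seed species
  Lig(l,l,l) 6.0e3
  Lyn(U,SH2) 2.8e4
  Syk(tSH2,lytk~Y,aloop~Y) 4.0e5
  Rec(a,b~Y,g~Y) 4.0e5
end seed species
begin observables
  Molecules RecPbeta Rec(b~pY)
  Molecules RecPgamma Rec(g~pY)
  Molecules RecSyk Rec(g~pY!1).Syk(tSH2!1)
  Molecules RecSykPS Rec(g~pY!1).Syk(tSH2!1,aloop~pY)
end observables
begin reaction rules
  Lig(l) + Rec(a) <-> Lig(l!1).Rec(a!1) kp1, km1
  Rec(b~Y) + Lyn(U,SH2) <-> Rec(b~Y!1).Lyn(U!1,SH2) kp2, km2
  Rec(b~Y) -> Rec(b~pY) pLb
  Rec(b~pY) -> Rec(b~Y) dm
  Rec(g~Y) -> Rec(g~pY) pLb
  Rec(g~pY) -> Rec(g~Y) dm
  Rec(b~pY) + Lyn(U,SH2) <-> Rec(b~pY!1).Lyn(U,SH2!1) kp2, km2
  Rec(g~pY) + Syk(tSH2) <-> Rec(g~pY!1).Syk(tSH2!1) kp2, km2
  Syk(tSH2!+,lytk~Y) -> Syk(tSH2!+,lytk~pY) pLS
  Syk(lytk~pY) -> Syk(lytk~Y) dc
  Syk(tSH2!+,aloop~Y) -> Syk(tSH2!+,aloop~pY) pLS
  Syk(aloop~pY) -> Syk(aloop~Y) dc
end reaction rules
end model
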