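# Synthetic EGFR-family base model: ligand binding, dimerization and
# receptor phosphorylation only.
begin model
begin parameters
  kp1 1.667e-06
  km1 0.06
  kp2 5.556e-06
  km2 0.1
  kp3 0.5
  km3 4.505
end parameters
begin molecule types
  egf(r)
  egfr(l,r,Y1068~Y~pY)
end molecule types
begin seed species
  egf(r) 1.2e6
  egfr(l,r,Y1068~Y) 1.8e5
end seed species
begin observables
  Molecules egfr_pY egfr(Y1068~pY)
end observables
begin reaction rules
  egf(r) + egfr(l,r) <-> egf(r!1).egfr(l!1,r) kp1, km1
  egfr(l!+,r) + egfr(l!+,r) <-> egfr(l!+,r!1).egfr(l!+,r!1) kp2, km2
  egfr(r!+,Y1068~Y) -> egfr(r!+,Y1068~pY) kp3
  egfr(Y1068~pY) -> egfr(Y1068~Y) km3
  egfr(r!+,Y1068~pY) -> egfr(r!+,Y1068~Y) km3
end reaction rules
end model
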