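# Co-flow program targeting the FF critical concentration: supercritical
# and subcritical stocks merged in the mixing channel.
streams:
  - {conc: 3.20, unit: mM, flow_ul_per_h: 2.2}
  - {conc: 1.60, unit: mM, flow_ul_per_h: 1.7}
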