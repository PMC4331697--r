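# Words (with trailing period) after which a period does not end a sentence.
e.g.
i.e.
al.
et.
etc.
fig.
figs.
eq.
eqs.
ref.
refs.
vs.
cf.
ca.
approx.
no.
dr.
prof.
mr.
mrs.
ms.
inc.
ltd.
st.
jr.
sr.
vol.
pp.
min.
max.
resp.
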