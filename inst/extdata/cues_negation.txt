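no
not
without
denies
never
absence of
##terminators
but
however
although
except
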