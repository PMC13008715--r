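raw_name,inn
TRACLEER,bosentan
STAYVEER,bosentan
BOSENTAN,bosentan
LETAIRIS,ambrisentan
VOLIBRIS,ambrisentan
AMBRISENTAN,ambrisentan
OPSUMIT,macitentan
MACITENTAN,macitentan
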