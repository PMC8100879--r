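# Placeholder risk key-phrase list (one phrase per line, UTF-8).
# Deployments replace this with their clinically curated lexicon.
quero morrer
me matar
suicídio
tirar minha vida
não aguento mais viver
kill myself
end my life
want to die
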