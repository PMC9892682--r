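# Cell-level overrides for irregular Spanish verbs: lemma|cell|surface
# cell is person.number.tense.mood for finite cells, or gerund/participle.
doler|third.singular.present.indicative|duele
doler|third.plural.present.indicative|duelen
doler|third.singular.present.subjunctive|duela
doler|third.plural.present.subjunctive|duelan
morir|gerund|muriendo
morir|participle|muerto
morir|third.singular.past.indicative|murió
morir|third.plural.past.indicative|murieron
morir|third.singular.present.indicative|muere
morir|third.plural.present.indicative|mueren
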