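# Reference rule sets: one sentence-scope include criterion OR-ing each
# topic lexicon, plus body-scope excludes for veterinary/animal-health
# confounders. Mirrors default_rules(); the file form exercises the rule
# grammar round trip.
topics:
  - topic: infections_deaths
    criteria:
      - scope: sentence
        polarity: include
        pattern: '"infection" OR "infections" OR "mortality" OR "quarantine" OR "icu" OR "contagion"'
      - scope: body
        polarity: exclude
        pattern: '"poultry"'
  - topic: mental_health
    criteria:
      - scope: sentence
        polarity: include
        pattern: '"psychological" OR "wellbeing" OR "morale" OR "distress" OR "coping" OR "resilience"'
  - topic: industrial_action
    criteria:
      - scope: sentence
        polarity: include
        pattern: '"strike" OR "walkout" OR "protest" OR "picket" OR "union" OR "demonstration"'
  - topic: vaccination
    criteria:
      - scope: sentence
        polarity: include
        pattern: '"vaccine" OR "vaccination" OR "vaccinated" OR "immunization" OR "jab" OR "inoculation"'
      - scope: body
        polarity: exclude
        pattern: '"veterinary" OR "livestock"'
  - topic: education
    criteria:
      - scope: sentence
        polarity: include
        pattern: '"curriculum" OR "internship" OR "residency" OR "faculty" OR "semester" OR "campus"'
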