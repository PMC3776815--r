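# Rendering dialects for self-reported anthropometrics in Q&A posts.
# Canonical dialects carry an explicit unit/keyword and are parseable by the
# precision-first extractor; ambiguous dialects drop the unit or gender word
# and are deliberately NOT parseable (the extractor omits rather than guesses).
# Placeholders: {age} years, {weight} lb, {kg} kg, {feet}/{inches}, {cm} cm,
# {gender} one of male/female/boy/girl/man/woman, {slang} one of guy/gal.
version: 1
age:
  canonical:
    - "I am {age} years old."
    - "{age} years old here."
    - "I'm {age} yrs old."
  ambiguous:
    - "I am {age}."
gender:
  canonical:
    - "I am a {gender}."
    - "I'm a {gender}."
  ambiguous:
    - "I'm a {slang}."
weight:
  canonical:
    - "I weigh {weight} pounds."
    - "I weigh {weight} lbs."
    - "My weight is {weight} lb."
    - "I weigh {kg} kg."
  ambiguous:
    - "I weigh {weight}."
height:
  canonical:
    - "I am {feet} foot {inches} inches tall."
    - "I'm {feet}'{inches}\"."
    - "I am {feet} ft {inches} in tall."
    - "I am {cm} cm tall."
  ambiguous:
    - "I am {feet} {inches}."
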