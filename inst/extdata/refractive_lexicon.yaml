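# Search terms used to detect refractive-error phenotypes in clinical
# synopsis text, grouped by refractive class. Matching is case-insensitive,
# whole-word; "-" joins letters, so "near-sighted" also matches "nearsighted".
# Edit or replace this file (see read_lexicon) to use a curated term list.
myopia:
  - myopia
  - myopic
  - near-sighted
  - near-sightedness
hyperopia:
  - hyperopia
  - hyperopic
  - hypermetropia
  - hypermetropic
  - far-sighted
  - far-sightedness
astigmatism:
  - astigmatism
  - astigmatic
ametropia_other:
  - ametropia
  - refractive error
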