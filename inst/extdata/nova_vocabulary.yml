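# Default ingredient-marker vocabulary for the NOVA rule ladder.
# Three pairwise-disjoint tag sets; the vocabulary is closed (an unknown tag
# on a record is an error). This list is an editorial default: edit or
# replace it to align with a particular NOVA guidance revision.
up_markers:
  - colouring
  - flavouring
  - emulsifier
  - thickener
  - non_caloric_sweetener
  - hydrogenated_oil
  - protein_isolate
  - maltodextrin
  - hfcs
processing_markers:
  - added_salt
  - added_sugar
  - added_oil
  - canned
  - fermented
  - smoked
culinary_substances:
  - vegetable_oil
  - butter
  - lard
  - table_sugar
  - salt
  - starch
  - honey
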