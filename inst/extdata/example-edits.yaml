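# illustrative reviewed edit script: each step is one curation judgment
# with a rationale, replayed in order by apply_edit_script()
- op: create_class
  name: steroid
  parents: [EX:0011]
  rationale: restore an intuitive checkpoint class removed by pruning
- op: move_term
  target: EX:0023
  new_parents: [steroid]
  rationale: progesterone belongs under the restored steroid class
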