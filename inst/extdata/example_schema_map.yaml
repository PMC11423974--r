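# Example schema map: bridges a foreign trial export onto the canonical
# schema. Omitted synonym tables fall back to the package defaults.
column_map:
  participant_id: subj
  task: block_task
  direction: dir
  speed: v
  target_distance: target_m
  response_distance: resp_m
task_synonyms:
  mtt: move_to_target
  adjust-target: adjust_target
direction_synonyms:
  fwd: forward
  bwd: backward
  upward: up
  downward: down
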