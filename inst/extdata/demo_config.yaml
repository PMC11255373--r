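# Demo run configuration: a small synthetic cohort with two fully
# rendered stereo tracks, completing end-to-end in well under a minute.
seed: 7
out_dir: pipeline_out
cohort:
  n_demo_tracks: 2
wand:
  n_poses: 80
  noise_sd: 0.5
smoothing:
  q: ~        # ~ = tune from the data
  r: ~
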