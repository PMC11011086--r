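# Example overnight-kennel scenario: one dog, night-vision mode, no
# nuisances.  A 5-minute session at 5 fps with a single 4-minute sleep
# bout flanked by wakefulness.
width: 160
height: 120
fps: 5
duration: 300
seed: 42
mode: NIGHT_GRAY
nuisance:
  shake_sd: 0
  flicker_amplitude: 0
  flicker_period: 30
  sensor_noise_sd: 0
dogs:
  - size: 40
    start: [60, 60]
    awake_motion_sd: 2
    awake_min_step: 2
    twitch_prob: 0
    twitch_amplitude: 2
    body_intensity: 200
    schedule:
      - {state: AWAKE, duration: 30}
      - {state: ASLEEP, duration: 240}
      - {state: AWAKE, duration: 30}
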