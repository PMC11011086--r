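# Two dogs sharing a pen in daylight (colour mode): one long sleeper and
# one late sleeper, far enough apart that tracks never overlap.
width: 200
height: 120
fps: 5
duration: 120
seed: 7
mode: DAY_COLOUR
nuisance:
  shake_sd: 0
  flicker_amplitude: 0
  flicker_period: 30
  sensor_noise_sd: 0
dogs:
  - size: 36
    start: [45, 60]
    territory: 25
    schedule:
      - {state: AWAKE, duration: 20}
      - {state: ASLEEP, duration: 100}
  - size: 36
    start: [150, 60]
    territory: 25
    schedule:
      - {state: AWAKE, duration: 50}
      - {state: ASLEEP, duration: 70}
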