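{
  "comment": "Frozen per-activity generator templates: fundamental frequency f0 (Hz), relative harmonic weights h2/h3 with harmonic phase phase2 (rad), and per-channel baseline offset, oscillation amplitude and Gaussian noise sd in physical units (kPa, g, dps, degrees). Static postures are constant-offset channels; gait activities are harmonic oscillations below the 10 Hz Nyquist limit of the 20 Hz node.",
  "SIT": {
    "f0": 0, "h2": 0, "h3": 0, "phase2": 0,
    "channels": {
      "pressure":    {"base": 4.0,  "amp": 0,   "noise": 0.2},
      "acc_x":       {"base": 0.05, "amp": 0,   "noise": 0.01},
      "acc_y":       {"base": 0.10, "amp": 0,   "noise": 0.01},
      "acc_z":       {"base": 0.98, "amp": 0,   "noise": 0.01},
      "gyro_x":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_y":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_z":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "euler_roll":  {"base": 2,    "amp": 0,   "noise": 0.8},
      "euler_pitch": {"base": 45,   "amp": 0,   "noise": 0.8},
      "euler_yaw":   {"base": 0,    "amp": 0,   "noise": 0.8}
    }
  },
  "STAND": {
    "f0": 0, "h2": 0, "h3": 0, "phase2": 0,
    "channels": {
      "pressure":    {"base": 7.0,  "amp": 0,   "noise": 0.2},
      "acc_x":       {"base": 0.02, "amp": 0,   "noise": 0.01},
      "acc_y":       {"base": 0.02, "amp": 0,   "noise": 0.01},
      "acc_z":       {"base": 1.00, "amp": 0,   "noise": 0.01},
      "gyro_x":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_y":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_z":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "euler_roll":  {"base": 1,    "amp": 0,   "noise": 0.8},
      "euler_pitch": {"base": 85,   "amp": 0,   "noise": 0.8},
      "euler_yaw":   {"base": 0,    "amp": 0,   "noise": 0.8}
    }
  },
  "LIE": {
    "f0": 0, "h2": 0, "h3": 0, "phase2": 0,
    "channels": {
      "pressure":    {"base": 2.0,  "amp": 0,   "noise": 0.2},
      "acc_x":       {"base": 0.90, "amp": 0,   "noise": 0.01},
      "acc_y":       {"base": 0.05, "amp": 0,   "noise": 0.01},
      "acc_z":       {"base": 0.20, "amp": 0,   "noise": 0.01},
      "gyro_x":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_y":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "gyro_z":      {"base": 0,    "amp": 0,   "noise": 1.5},
      "euler_roll":  {"base": 75,   "amp": 0,   "noise": 0.8},
      "euler_pitch": {"base": 5,    "amp": 0,   "noise": 0.8},
      "euler_yaw":   {"base": 0,    "amp": 0,   "noise": 0.8}
    }
  },
  "WALK": {
    "f0": 1.2, "h2": 0.3, "h3": 0.15, "phase2": 0,
    "channels": {
      "pressure":    {"base": 10.0, "amp": 2.5, "noise": 0.4},
      "acc_x":       {"base": 0.05, "amp": 0.25, "noise": 0.05},
      "acc_y":       {"base": 0.10, "amp": 0.20, "noise": 0.05},
      "acc_z":       {"base": 1.00, "amp": 0.35, "noise": 0.05},
      "gyro_x":      {"base": 0,    "amp": 50,  "noise": 8},
      "gyro_y":      {"base": 0,    "amp": 35,  "noise": 8},
      "gyro_z":      {"base": 0,    "amp": 25,  "noise": 8},
      "euler_roll":  {"base": 3,    "amp": 6,   "noise": 1.5},
      "euler_pitch": {"base": 70,   "amp": 9,   "noise": 1.5},
      "euler_yaw":   {"base": 0,    "amp": 4,   "noise": 1.5}
    }
  },
  "RUN": {
    "f0": 2.5, "h2": 0.3, "h3": 0.15, "phase2": 0,
    "channels": {
      "pressure":    {"base": 16.0, "amp": 5.0, "noise": 0.7},
      "acc_x":       {"base": 0.05, "amp": 0.70, "noise": 0.10},
      "acc_y":       {"base": 0.10, "amp": 0.50, "noise": 0.10},
      "acc_z":       {"base": 1.00, "amp": 0.90, "noise": 0.10},
      "gyro_x":      {"base": 0,    "amp": 140, "noise": 15},
      "gyro_y":      {"base": 0,    "amp": 100, "noise": 15},
      "gyro_z":      {"base": 0,    "amp": 70,  "noise": 15},
      "euler_roll":  {"base": 4,    "amp": 10,  "noise": 2.5},
      "euler_pitch": {"base": 65,   "amp": 15,  "noise": 2.5},
      "euler_yaw":   {"base": 0,    "amp": 7,   "noise": 2.5}
    }
  },
  "UP": {
    "f0": 1.0, "h2": 0.6, "h3": 0.2, "phase2": 0.7,
    "channels": {
      "pressure":    {"base": 18.0, "amp": 4.0, "noise": 0.5},
      "acc_x":       {"base": 0.08, "amp": 0.35, "noise": 0.06},
      "acc_y":       {"base": 0.10, "amp": 0.25, "noise": 0.06},
      "acc_z":       {"base": 1.00, "amp": 0.55, "noise": 0.06},
      "gyro_x":      {"base": 0,    "amp": 80,  "noise": 9},
      "gyro_y":      {"base": 0,    "amp": 55,  "noise": 9},
      "gyro_z":      {"base": 0,    "amp": 35,  "noise": 9},
      "euler_roll":  {"base": 5,    "amp": 7,   "noise": 1.2},
      "euler_pitch": {"base": 95,   "amp": 12,  "noise": 1.2},
      "euler_yaw":   {"base": 0,    "amp": 5,   "noise": 1.2}
    }
  },
  "DOWN": {
    "f0": 1.0, "h2": 0.6, "h3": 0.2, "phase2": -0.7,
    "channels": {
      "pressure":    {"base": 6.0,  "amp": 3.0, "noise": 0.5},
      "acc_x":       {"base": 0.08, "amp": 0.30, "noise": 0.06},
      "acc_y":       {"base": 0.10, "amp": 0.25, "noise": 0.06},
      "acc_z":       {"base": 1.00, "amp": 0.50, "noise": 0.06},
      "gyro_x":      {"base": 0,    "amp": 70,  "noise": 9},
      "gyro_y":      {"base": 0,    "amp": 50,  "noise": 9},
      "gyro_z":      {"base": 0,    "amp": 30,  "noise": 9},
      "euler_roll":  {"base": 3,    "amp": 7,   "noise": 1.2},
      "euler_pitch": {"base": 40,   "amp": 10,  "noise": 1.2},
      "euler_yaw":   {"base": 0,    "amp": 5,   "noise": 1.2}
    }
  }
}
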