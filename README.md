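# aortasim

An in-silico digital twin of a bench cardiovascular simulator: it
generates central aortic blood-pressure waveforms by superposing forward
and reflected pressure waves in a geometrically and mechanically faithful
1-D model of an artificial aorta, and provides the pulse-wave-analysis
toolkit needed to read those waveforms the way a physiologist would.

It is written for people who work with mock circulatory loops, vascular
phantoms, or pulse-wave-analysis algorithms and want a fast, fully
deterministic software counterpart of the hardware: every experiment —
heart-rate, stroke-volume, peripheral-resistance and chamber-pressure
sweeps — is a function call that returns a tidy table.

## The model in brief

Pressure waves travel along the artificial aorta (743 mm total: a
half-circle arch of 50 mm radius and 28 mm bore, a 512 mm abdominal
segment tapering 26 → 16 mm, a femoral branch beyond the 80° bifurcation;
wall 2 mm of strain-softening silicone) at the Moens–Korteweg speed

    PWV = sqrt( E h / (rho_f D (1 - nu^2)) )

with `E` the wall modulus under the current transmural pressure
(TP = IVP − EVP; the compliance chamber holds TP = 0 so the silicone
stays at its zero-strain modulus of 346 kPa), `h = 2` mm, `rho_f = 1000`
kg/m³, `nu = 0.5`, and a pulse-averaged effective diameter
`D_eff = 21.8` mm. The ventricular piston ejects 70 mL at 75 BPM through
a one-way valve; the pulsatile flow launches a forward wave `Zc·(Q − CO)`
riding on a Windkessel relaxation; the wave reflects at the bifurcation
against the peripheral load (`Γ = (R_T − Zc)/(R_T + Zc)`, ball-valve
orifice law `R(o) = R_ref (0.85/(1−o))²`) and superposes with the forward
train at each sensor. Waveform indices follow the clinical definitions:
`PP = SBP − DBP`, `MAP = (SBP + 2 DBP)/3`, `AIx = 100·AP/PP` with AP the
rise from the systolic shoulder to the peak, and PWV measured
foot-to-foot over the 551 mm between the arch and bifurcation sensors.

Four lumped constants (total resistance, compliance, termination
resistance, forward amplitude) are calibrated once, deterministically,
against the human-standard anchors SBP 120 / DBP 80 / AIx 13.3 % and ship
frozen; everything downstream is reproducible bit for bit. The methods
vignette (`vignettes/simulator-methods.Rmd`) derives and defends every
choice.

## Worked example

```r
library(aortasim)

sim <- simulate_aorta()          # standard configuration: HR 75, SV 70,
print(sim)                       # 15 % occlusion, TP = 0
#> <aorta_simulation> HR 75, SV 70, occlusion 15%, TP 0.0 mmHg
#>   wave speed 6.506 m/s (E_eff 346 kPa), Zc 0.1307 mmHg.s/mL, Gamma_ab 0.272
#>   aa: <pressure_waveform> 9600 samples @ 4000 Hz (2.40 s) at s = 0.000 m; range 78.4-120.0 mmHg
#>   ab: <pressure_waveform> 9600 samples @ 4000 Hz (2.40 s) at s = 0.551 m; range 75.7-127.2 mmHg

extract_features(sim$waveforms$aa)
#> <waveform_features> (1 beats averaged)
#>   SBP 120.0  DBP 80.0  PP 40.0 mmHg
#>   MAP 93.3 (formula) / 102.7 (integral) mmHg
#>   AP 5.3 mmHg  AIx 13.3%

measure_ptt(sim$waveforms$aa, sim$waveforms$ab, 0.551)
#> <ptt_measurement> distance 0.551 m, PTT 0.0848 s (2 beats), PWV 6.50 m/s

moens_inverse_e(6.54, h = 0.002, rho = 1000, D = 0.0218, nu = 0.5) / 1000
#> [1] 349.6578   # kPa of silicone needed for the 6.54 m/s design speed
```

Reading the output: the root (`aa`) waveform sits at the human standard
120/80 mmHg with mean pressure 93.3 mmHg by the clinical formula; the
augmentation pressure of 5.3 mmHg on a 40 mmHg pulse gives the mid-range
augmentation index of 13.3 %; and the foot-to-foot wave speed of 6.50 m/s
sits within 0.05 m/s of the 6.54 m/s design target. Closer to the
bifurcation (`ab`) the pulse is amplified, as it should be.

The parameter sweeps and their direction checks:

```r
tabs <- lapply(c(hr = "hr", pr = "pr", tp = "tp"), run_sweep)
trend_report(tabs)        # pass/fail per expected direction, with values
```

A thin command-line front end over the same functions lives at
`inst/cli/aortasim.R` (`simulate`, `features`, `sweep`, `calibrate`,
`fixtures` subcommands), reading and writing YAML configs and tidy CSV.

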