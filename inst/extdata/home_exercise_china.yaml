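# Bundled case study: development strategy of home-based exercise in China.
# 13 SWOT factors, one expert pairwise-comparison matrix per group (Saaty
# scale), and 0-5 estimated strengths. Strengths for W/T are magnitudes; the
# negative sign is applied by the package from group membership.
metadata:
  title: Development strategy of home-based exercise in China (SWOT-AHP)
  analyst: expert panel (n = 10), sports and medical science
  date: "2020"
options:
  reciprocity_tol: 1.0e-06
  strict_saaty: false
  cr_gate: error
  digits: 4
groups:
  S:
    factors:
      - id: S1
        label: Construction of a leading sports nation
        description: National policy drive promoting the sports industry.
        strength: 5
      - id: S2
        label: Increased awareness of exercise
        description: Growing public recognition of the value of physical health.
        strength: 4
      - id: S3
        label: Time freedom
        description: Exercise at home fits office workers' schedules.
        strength: 3
      - id: S4
        label: Low cost and convenient
        description: Light or no equipment needed; independent of weather.
        strength: 2
    matrix:
      - [1, 2, 4, 5]
      - [1/2, 1, 3, 4]
      - [1/4, 1/3, 1, 2]
      - [1/5, 1/4, 1/2, 1]
  W:
    factors:
      - id: W1
        label: Limited space leads to fewer sports methods
        description: Home settings restrict equipment and exercise options.
        strength: 3
      - id: W2
        label: Monotonous and boring form of exercise
        description: Indoor routines are repetitive and can cause boredom.
        strength: 2
      - id: W3
        label: Less theoretical research and insufficient professional talents
        description: Little targeted research and few cross-disciplinary specialists.
        strength: 4
    matrix:
      - [1, 2, 1/4]
      - [1/2, 1, 1/3]
      - [4, 3, 1]
  O:
    factors:
      - id: O1
        label: Support provided by the government
        description: Official promotion of scientific home-based exercise methods.
        strength: 3
      - id: O2
        label: The stable development of sports industry
        description: Steady growth of the sports industry and online sports market.
        strength: 2
      - id: O3
        label: The rapid development of intelligent sports
        description: Wearables, smart equipment and virtual-reality sports products.
        strength: 5
    matrix:
      - [1, 3, 1/4]
      - [1/3, 1, 1/6]
      - [4, 6, 1]
  T:
    factors:
      - id: T1
        label: Noise
        description: Indoor exercise may disturb neighbours.
        strength: 1
      - id: T2
        label: Easy to be slack at home
        description: The home environment invites laziness.
        strength: 3
      - id: T3
        label: Fading enthusiasm for home-based exercise
        description: Interest may drop once outdoor venues reopen.
        strength: 4
    matrix:
      - [1, 1/3, 1/4]
      - [3, 1, 1/2]
      - [4, 2, 1]
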