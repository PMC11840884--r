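# shared fixtures: one profile per parameterized pairing
bird_1kg   <- animal_profile(1, "bird")
mammal_1kg <- animal_profile(1, "mammal")
fish_1kg   <- animal_profile(1, "fish")

profiles_at <- function(mass) list(
  bird = animal_profile(mass, "bird"),
  mammal = animal_profile(mass, "mammal"),
  fish = animal_profile(mass, "fish"))

# log-spaced mass grid
mass_grid <- function(from, to, n = 25) exp(seq(log(from), log(to), length.out = n))

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# closed-form inversion of the published running cost per metre:
# J/m = a14*BMR/v + a10*M^b11  =>  v = a14*BMR / (J/m - a10*M^b11)
backsolve_running_speed <- function(mass, joules_per_metre,
                                    p = dispersal_params()) {
  bmr <- p$a5 * mass^p$b5
  p$a14 * bmr / (joules_per_metre - p$a10 * mass^p$b11)
}
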