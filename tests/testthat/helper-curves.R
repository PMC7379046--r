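# Shared fixtures: small deterministic curves built in code.

# exactly linear curve sigma = slope * eps
linear_curve <- function(slope = 10, n = 101, eps_max = 1, id = "linear") {
  eps <- seq(0, eps_max, length.out = n)
  stress_strain_curve(eps, slope * eps, specimen_id = id)
}

# bilinear curve: slope s1 up to eps_break, then slope s2
bilinear_curve <- function(s1 = 10, s2 = 1, eps_break = 0.1, n = 2001,
                           eps_max = 1) {
  eps <- seq(0, eps_max, length.out = n)
  sig <- ifelse(eps <= eps_break, s1 * eps,
                s1 * eps_break + s2 * (eps - eps_break))
  stress_strain_curve(eps, sig, specimen_id = "bilinear")
}

# a small specimen geometry with volume fraction 0.30
demo_geometry <- function() {
  specimen_geometry(gauge_length_mm = 10, area_mm2 = 1, weight_mg = 3.54,
                    density_mg_mm3 = 1.18, specimen_class = "random_mat")
}
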