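# Minimal ad-hoc preset for generating time courses from arbitrary truths.
make_truth_preset <- function(model, params, analyte = "starch",
                              name = "synthetic") {
  list(name = name, pulse = "XX",
       kinetics = stats::setNames(list(list(model = model, params = params)),
                                  analyte),
       hardness = c(Ci = 140, Cf = 42, k = 0.05))
}

# Central finite difference of a fitted curve.
fd_slope <- function(fit, t, h = 1e-5) {
  (predict(fit, t + h) - predict(fit, max(t - h, 0))) /
    (h + min(t, h))
}
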