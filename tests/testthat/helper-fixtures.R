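# Shared fixtures: exact series generation from a known model, and the
# published fitted parameters used as ground truth for recovery tests.

ref_params <- reference_release_parameters()

ref_row <- function(formulation, method) {
  ref_params[ref_params$formulation == formulation &
               ref_params$method == method, , drop = FALSE]
}

exact_series <- function(C2_edge, rate_a, h, span = 7, t0 = 0) {
  m <- first_order_model(C2_edge = C2_edge, rate_a = rate_a, t0 = t0)
  evaluate_release_curve(m, seq(t0, t0 + span, by = h))
}

# step size convention used throughout the recovery tests: fine grid for the
# first-order stencil, coarser for the fourth-order one
h_for_method <- function(method) if (method == "O(h)") 0.001 else 0.01
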