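#!/usr/bin/env Rscript
# Build the synthetic model set used by the whole workflow: an idealized
# canonical nucleosome, a CENP-A nucleosome with flexible DNA ends, bridged
# two-nucleosome stacks with 0/1/2 factor copies, and the three fiber
# presets. Writes coordinate fixtures (+ chain-role sidecars) and per-bp
# tables under results/models/.

suppressMessages(library(nucstack))
out <- file.path("results", "models")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("== canonical and CENP-A nucleosomes ==\n")
can <- build_nucleosome()
cen <- build_nucleosome(cenpa_nucleosome_spec())
for (x in list(list(can, "nucleosome_canonical"),
               list(cen, "nucleosome_cenpa"))) {
  write_fixture(x[[1]], file.path(out, paste0(x[[2]], ".pdb")))
  write_bp_table(pair_base_steps(x[[1]], "nuc1"),
                 file.path(out, paste0(x[[2]], "_bp.csv")))
}
s_cen <- pair_base_steps(cen, "nuc1")
cat(sprintf("  canonical: %d bp, all bound; CENP-A: %d of %d bp bound\n",
            147L, sum(s_cen$stably_bound), nrow(s_cen)))

cat("== bridged stacks (0, 1, 2 factor copies) ==\n")
for (nf in 0:2) {
  st <- build_stack(stack_spec(n_factors = nf))
  write_fixture(st, file.path(out, sprintf("stack_%dfactor.pdb", nf)))
  sp <- step_parameters(nucleosome_frame(st, "nuc1"),
                        nucleosome_frame(st, "nuc2"))
  cat(sprintf("  %d-factor stack: rise %.1f A, tilt %.1f deg, twist %.1f deg\n",
              nf, sp$rise, sp$tilt, sp$twist))
}

cat("== fiber presets ==\n")
for (p in c("cenpn_like", "h1_like", "ladder")) {
  fib <- build_fiber(fiber_spec(preset = p))
  write_fixture(fib, file.path(out, paste0("fiber_", p, ".cif")))
  ord <- order_nucleosomes(fib)
  cat(sprintf("  %s: %d nucleosomes, %d ordered\n", p, nrow(ord),
              sum(ord$ordered_flag)))
}
cat("fixtures written to", out, "\n")
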