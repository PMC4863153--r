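# shared small fixtures; heavier simulated objects are built once here and
# reused across test files
water <- material_water()
proton <- projectile("proton")
carbon <- projectile("carbon")

# a quiet wrapper: low-energy shell-correction clamp warnings are expected
# whenever full-range tables are built
quiet <- function(expr) suppressWarnings(expr)

ledger_closure <- function(grid) {
  led <- grid$ledger
  (led$deposited + led$escaped_geometry + led$nuclear_escaped +
     led$tail_escaped) / led$input
}
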