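# Small in-code fixtures shared across test files.

make_peaks <- function(mz, rt, energy = "low", system = "in_vivo",
                       sample_id = "s1", intensity = 1e5) {
  peak_table(data.frame(sample_id = sample_id, system = system,
                        energy = energy, mz = mz, rt_min = rt,
                        intensity = intensity, stringsAsFactors = FALSE))
}

# Independent element-by-element mass oracle: literal IUPAC monoisotopic
# masses, summed without going through parse_formula/formula_mass.
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, Na = 0, K = 0) {
  C * 12.000000 + H * 1.007825 + N * 14.003074 + O * 15.994915 +
    Na * 22.989770 + K * 38.963707
}

# A (class, Rt)-separable truth panel: every metabolite class/Rt pair is
# unique across systems, so class + Rt joining identifies each record.
separable_panel <- function() {
  data.frame(
    id = sprintf("T%02d", 1:9),
    class = c("ART + O", "ART + O", "ART + O2", "de-ART", "de-ART + O",
              "DHA", "DHA + O", "DHA-O", "DHA-O + O"),
    ion = c("M+H", "M+Na", "M+Na", "M+H", "M+Na", "M+Na", "M+Na", "M+Na",
            "M+Na"),
    rt_min = c(2.6, 4.0, 2.0, 8.3, 5.6, 7.0, 3.1, 6.6, 5.8),
    in_vivo = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    in_vitro = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
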