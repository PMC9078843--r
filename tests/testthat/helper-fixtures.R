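# Shared fixtures, built in code at test time.

# Minimal valid PSM table; fields overridable per record via ...
make_psms <- function(n = 1, delta_mass = 15.9949, residue = "W",
                      score = 350, delta_mod_score = 20, fdr_2d = 0.001,
                      protein = "P1", site = 10L, sample_id = "P01_T",
                      group = "tumor") {
  data.frame(spectrum_id = sprintf("S%04d", seq_len(n)),
             peptide = "ACDWK",
             protein = protein, site = site, residue = residue,
             delta_mass = delta_mass, score = score,
             delta_mod_score = delta_mod_score, fdr_2d = fdr_2d,
             sample_id = sample_id, group = group,
             stringsAsFactors = FALSE)
}

# Tiny modification database from (name, composition, class, plausible)
make_db <- function(names, compositions, classes = "Reactive species",
                    plausible = TRUE, source = "preknown", steps = 1L) {
  df <- data.frame(name = names, composition = compositions,
                   class = classes, plausible = plausible, source = source,
                   steps = steps, stringsAsFactors = FALSE)
  df$delta <- vapply(df$composition,
                     function(s) monoisotopic_mass(parse_composition(s)),
                     numeric(1))
  df[c("name", "composition", "delta", "class", "plausible", "source",
       "steps")]
}

# Golden annotation rows used across tests: columns are the printed
# chemical formula, printed monoisotopic mass, printed error, and the
# observed delta-mass centre. Rows whose printed mass is inconsistent with
# the formula (hydroxykynurenine, and the -124.1118 unknown whose printed
# formula dropped a sign) are excluded.
golden_rows <- function() {
  data.frame(
    formula = c("O", "O(2)", "C(-1)O", "C(3)O(5)", "C(22)H(26)O(4)",
                "C(16)H(24)N(4)O(6)", "C(24)H(32)O(7)", "C(1)H(4)N(2)O(3)",
                "C(9)H(18)N(4)O(4)", "C(12)H(20)N(6)O(4)", "C(26)H(39)NO(8)",
                "C(3)H(5)NOS", "HC(-5)N(-1)", "C(-6)H(-5)N(-1)O(2)",
                "C(-1)H(-1)N(-1)O(2)", "C(-4)HN(-1)OS", "H(-1)N(-1)O(3)",
                "C(-1)H(3)N(-1)O(7)", "CH(5)N(-1)O(4)",
                "H(11)C(6)NO(3)S(2)", "OH(-1)", "C(14)H(13)N",
                "C(10)H(14)NO(6)"),
    printed_mass = c(15.9949, 31.9898, 3.9949, 115.9746, 354.1831,
                     368.1696, 432.2148, 92.0222, 246.1328, 312.1546,
                     493.2676, 103.0092, -72.9953, -59.0524, 4.9790,
                     -13.0283, 32.9739, 88.9848, 67.0157, 209.0180,
                     14.9871, 195.1048, 244.0821),
    printed_error = c(0, 1.00e-4, 4.00e-4, 8.00e-4, -1.23e-2, 2.00e-4,
                      -2.00e-4, 5.50e-3, 4.50e-3, -1.00e-4, -1.90e-3,
                      -4.00e-4, -8.00e-4, 1.80e-3, 2.00e-4, -2.50e-3,
                      9.00e-4, 9.40e-3, -9.90e-3, -1.00e-4, -4.40e-3,
                      -7.00e-4, 5.50e-3),
    delta_mass = c(15.9949, 31.9899, 3.9953, 115.9754, 354.1708, 368.1698,
                   432.2146, 92.0277, 246.1373, 312.1545, 493.2657,
                   103.0088, -72.9961, -59.0506, 4.9792, -13.0308, 32.9748,
                   88.9942, 67.0058, 209.0179, 14.9827, 195.1041,
                   244.0876),
    stringsAsFactors = FALSE)
}

# The 25-row classification/frequency columns of the published-style variant summary
class_frequency_fixture <- function() {
  data.frame(
    class = c(rep("Reactive species", 11), rep("Chemical derivative", 2),
              rep("AA substitution", 7), "Artefact", rep("Unknown", 4)),
    frequency = c(2872, 5965, 2029, 45, 2, 2, 4, 1, 1, 1, 1,
                  35, 2,
                  22, 16, 32, 11, 204, 20, 16,
                  76,
                  10, 352, 1, 5),
    stringsAsFactors = FALSE)
}
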