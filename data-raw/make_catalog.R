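# Regenerates the packaged example catalog (inst/extdata/catalog).
# Identifiers are real reagents from the nickel-catalyzed amine-acid
# coupling space; descriptor values are synthetic draws with a fixed seed
# (real physical descriptors are not required for testing the protocol).
set.seed(20260910)

precat <- c("NiCl2.dme", "NiBr2.dme", "NiI2", "NiBr2.diglyme", "Ni.acac.2")

ligands <- sprintf("L%d", 1:29)
lig_desc <- matrix(round(rnorm(29 * 4), 4), 29, 4,
                   dimnames = list(NULL, paste0("d", 1:4)))

additives <- data.frame(
  id     = c("none", "MgCl2", "MgBr2", "MgI2", "ZnCl2", "ZnBr2", "LiCl",
             "LiBr", "NaI", "NaBr", "KBr", "KI", "TMSCl", "NBu4Br"),
  cation = c("none", "Mg", "Mg", "Mg", "Zn", "Zn", "Li",
             "Li", "Na", "Na", "K", "K", "TMS", "NBu4"),
  anion  = c("none", "Cl", "Br", "I", "Cl", "Br", "Cl",
             "Br", "I", "Br", "Br", "I", "Cl", "Br"))

solvents <- c("THF", "2-MeTHF", "dioxane", "DME", "diglyme", "DMA", "NMP",
              "MeCN", "EtOAc")
solv_desc <- matrix(round(rnorm(9 * 3), 4), 9, 3,
                    dimnames = list(NULL, paste0("d", 1:3)))

substrates <- data.frame(
  id   = c("A-ala", "A-indanyl", "A-mbn", "A-mex", "C-chx", "C-ala"),
  role = c("acid", "amine", "amine", "amine", "acid", "acid"))
sub_desc <- matrix(round(rnorm(nrow(substrates) * 2), 4), nrow(substrates), 2,
                   dimnames = list(NULL, paste0("d", 1:2)))

out <- file.path("inst", "extdata", "catalog")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(data.frame(id = precat), file.path(out, "precatalysts.csv"), row.names = FALSE)
write.csv(cbind(data.frame(id = ligands), lig_desc), file.path(out, "ligands.csv"),
          row.names = FALSE)
write.csv(additives, file.path(out, "additives.csv"), row.names = FALSE)
write.csv(cbind(data.frame(id = solvents), solv_desc), file.path(out, "solvents.csv"),
          row.names = FALSE)
write.csv(cbind(substrates, sub_desc), file.path(out, "substrates.csv"),
          row.names = FALSE)
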