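# Shared toy fixtures, built in code.

chain_network <- function() {
  parse_network(c("U: A_ext -> A | irrev | exchange",
                  "C1: A -> B | irrev | core",
                  "X: B -> B_ext | irrev | exchange"))
}

# two parallel routes from A to D: exactly two elementary modes
diamond_network <- function() {
  parse_network(c("U: E_ext -> A | irrev | exchange",
                  "R1: A -> B | irrev | core",
                  "R2: A -> C | irrev | core",
                  "R3: B -> D | irrev | core",
                  "R4: C -> D | irrev | core",
                  "X: D -> D_ext | irrev | exchange"))
}

diamond_compositions <- function() {
  data.frame(id = c("E_ext", "A", "B", "C", "D", "D_ext"),
             C = 2, H = 0, O = 0, N = 0, S = 0, P = 0,
             stringsAsFactors = FALSE)
}

# branched fermentation toy: 6 C substrate to either a 2-C product (with CO2
# loss) or full secretion; known yields by hand
toy_ferment_network <- function() {
  net <- parse_network(c(
    "U: S_ext -> S | irrev | exchange",
    "R1: S -> 2 P + 2 C1 | irrev | core",
    "XP: P -> P_ext | irrev | exchange",
    "XC: C1 -> C_ext | irrev | exchange"))
  set_compositions(net, data.frame(
    id = c("S_ext", "S", "P", "P_ext", "C1", "C_ext"),
    C = c(6, 6, 2, 2, 1, 1), H = c(12, 12, 6, 6, 0, 0),
    O = c(6, 6, 1, 1, 2, 2), N = 0, S = 0, P = 0, stringsAsFactors = FALSE))
}

expect_same_modes <- function(a, b) {
  expect_identical(a$fluxes, b$fluxes)
}
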