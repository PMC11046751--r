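# 01 - simulate the study population.
#
# Draws the full synthetic population (tracks + ground-truth ledger) and
# writes the raw tracks, the per-agent truths, and the true migration
# events. The ledger is what later recovery checks compare against.

source("analysis/00_config.R")

sim <- simulate_population(POPULATION, SEED)

write_tracks(sim$tracks, tracks_path("raw"))
write.csv(sim$ledger$agents, res_path("ledger_agents.csv"), row.names = FALSE)
write.csv(sim$ledger$events, res_path("ledger_events.csv"), row.names = FALSE)

cat(sprintf("simulated %d tracks (%d fixes total)\n",
            length(sim$tracks),
            sum(vapply(sim$tracks, nrow, integer(1)))))
cat(sprintf("true migration events in ledger: %d\n",
            nrow(sim$ledger$events)))
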