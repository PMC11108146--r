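# Relation sentence templates for the synthetic corpus generator.
# Placeholders: {agent} {verb} {target} {context} {serial}.
# Every template places the trigger verb directly between agent and target
# so the rule-based relation scorer's forward pattern applies.
{agent} {verb} {target} during {context} in assay {serial}.
Our analysis showed that {agent} {verb} {target} under {context} in replicate {serial}.
{agent} directly {verb} {target} in cells undergoing {context} (experiment {serial}).
In this strain, {agent} strongly {verb} {target} throughout {context} in trial {serial}.
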