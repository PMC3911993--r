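source,target,evidence
RSS174,RLS2,RSS up-regulation of RLS synthesis
RSS175,RLS2,RSS up-regulation of RLS synthesis
RLS2,RLS2,RLS self-feedback when in excess
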