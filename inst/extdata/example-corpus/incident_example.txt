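An elderly patient with severe pain was prescribed 10 mg of morphine to be given subcutaneously. The nurse covering multiple patients on a busy ward administered the dose intravenously. The error was identified immediately and the patient was monitored; no harm occurred.
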